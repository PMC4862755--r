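#' Squared allelic correlation from haplotypes
#'
#' Computes r-squared between two SNPs from phased 0/1 haplotype
#' vectors: `r2 = D^2 / (pA (1-pA) pB (1-pB))` with
#' `D = pAB - pA * pB`.
#'
#' @param hap_a,hap_b 0/1 vectors of equal length (>= 2 haplotypes).
#' @return r-squared in \[0, 1\].
#' @examples
#' r2_from_haplotypes(c(1, 1, 0, 0, 0, 0), c(1, 0, 0, 0, 0, 0))  # 0.4
#' @export
r2_from_haplotypes <- function(hap_a, hap_b) {
  if (length(hap_a) != length(hap_b)) stop("haplotype vectors differ in length")
  if (length(hap_a) < 2) stop("need at least 2 haplotypes")
  if (!all(hap_a %in% c(0, 1)) || !all(hap_b %in% c(0, 1))) {
    stop("haplotypes must be coded 0/1")
  }
  p_a <- mean(hap_a)
  p_b <- mean(hap_b)
  if (p_a %in% c(0, 1) || p_b %in% c(0, 1)) {
    stop("r-squared undefined for a monomorphic SNP")
  }
  d <- mean(hap_a * hap_b) - p_a * p_b
  d^2 / (p_a * (1 - p_a) * p_b * (1 - p_b))
}

#' Construct an LD panel
#'
#' An LD panel provides pairwise r-squared lookups, either from a
#' precomputed table of r-squared triples or from a haplotype matrix
#' (haplotypes in rows, SNPs in columns) from which r-squared is
#' computed on demand via [r2_from_haplotypes()].
#'
#' @param r2_table Optional `data.frame` with columns `id1`, `id2`, `r2`.
#'   Pairs not listed have r-squared 0.
#' @param haplotypes Optional 0/1 matrix with SNP ids as column names.
#' @param ids Optional character vector of all SNP ids known to the
#'   panel; defaults to the ids present in the table / matrix columns.
#' @return An `ld_panel` object.
#' @export
ld_panel <- function(r2_table = NULL, haplotypes = NULL, ids = NULL) {
  if (is.null(r2_table) == is.null(haplotypes)) {
    stop("supply exactly one of r2_table or haplotypes")
  }
  if (!is.null(r2_table)) {
    stopifnot(all(c("id1", "id2", "r2") %in% names(r2_table)))
    if (any(r2_table$r2 < 0 | r2_table$r2 > 1)) stop("r2 must lie in [0, 1]")
    if (is.null(ids)) ids <- unique(c(r2_table$id1, r2_table$id2))
    # symmetric adjacency: partner list per SNP
    both <- data.frame(
      a = c(r2_table$id1, r2_table$id2),
      b = c(r2_table$id2, r2_table$id1),
      r2 = c(r2_table$r2, r2_table$r2),
      stringsAsFactors = FALSE
    )
    both <- both[both$a != both$b, , drop = FALSE]
    partners <- split(both[c("b", "r2")], both$a)
    # integer adjacency for vectorized whole-pool operations
    adj <- data.frame(a = match(both$a, ids), b = match(both$b, ids),
                      r2 = both$r2)
    structure(list(kind = "table", partners = partners, adj = adj,
                   ids = ids),
              class = "ld_panel")
  } else {
    if (is.null(colnames(haplotypes))) stop("haplotype matrix needs SNP ids as colnames")
    if (is.null(ids)) ids <- colnames(haplotypes)
    structure(list(kind = "haplotypes", hap = haplotypes, ids = ids),
              class = "ld_panel")
  }
}

#' Pairwise r-squared from an LD panel
#'
#' @param panel An [ld_panel()].
#' @param a,b SNP ids.
#' @return r-squared; 1 when `a == b`, 0 for pairs absent from a table
#'   panel.
#' @export
panel_r2 <- function(panel, a, b) {
  stopifnot(inherits(panel, "ld_panel"))
  if (a == b) return(1)
  if (panel$kind == "table") {
    p <- panel$partners[[a]]
    if (is.null(p)) return(0)
    hit <- match(b, p$b)
    if (is.na(hit)) 0 else p$r2[hit]
  } else {
    r2_from_haplotypes(panel$hap[, a], panel$hap[, b])
  }
}

#' LD partners of a SNP above an r-squared cutoff
#'
#' @param panel An [ld_panel()].
#' @param id SNP id.
#' @param r2_min r-squared cutoff; partners require `r2 > r2_min`
#'   (strict).
#' @return Character vector of partner ids (excluding `id`).
#' @export
ld_partners <- function(panel, id, r2_min) {
  stopifnot(inherits(panel, "ld_panel"))
  if (!id %in% panel$ids) stop("SNP absent from LD panel: ", id)
  if (panel$kind == "table") {
    p <- panel$partners[[id]]
    if (is.null(p)) return(character(0))
    p$b[p$r2 > r2_min]
  } else {
    others <- setdiff(colnames(panel$hap), id)
    r2 <- vapply(others, function(o) r2_from_haplotypes(panel$hap[, id],
                                                        panel$hap[, o]),
                 numeric(1))
    others[r2 > r2_min]
  }
}

#' Expand a lead SNP into an LD locus
#'
#' A locus is a lead variant plus every panel SNP in strong LD with it;
#' membership requires `r2 > r2_min` (strict, so a partner at exactly
#' the cutoff is excluded).
#'
#' @param lead Lead SNP id.
#' @param panel An [ld_panel()].
#' @param r2_min LD threshold (default 0.8).
#' @return A `locus` list with `lead`, `members` (including the lead)
#'   and `r2_threshold`.
#' @export
expand_locus <- function(lead, panel, r2_min = 0.8) {
  members <- union(lead, ld_partners(panel, lead, r2_min))
  structure(list(lead = lead, members = members, r2_threshold = r2_min),
            class = "locus")
}

#' Merge loci with correlated leads and deduplicate shared members
#'
#' Loci whose leads are themselves in LD (`r2 > r2_min`) are merged into
#' a single locus. After merging, a SNP shared between the member sets
#' of two distinct loci is assigned to exactly one of them, uniformly at
#' random, so the output loci are disjoint SNP sets.
#'
#' @param loci List of `locus` objects built at the same threshold.
#' @param panel An [ld_panel()].
#' @param seed Integer seed for the random shared-member assignment.
#' @param r2_min Lead-lead merge threshold (default 0.8).
#' @return List of disjoint `locus` objects.
#' @export
merge_and_deduplicate <- function(loci, panel, seed = 1L, r2_min = 0.8) {
  n <- length(loci)
  if (n == 0) return(loci)
  # union-find over loci with correlated leads
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n - 1)) {
    for (j in seq((i + 1), n)) {
      if (panel_r2(panel, loci[[i]]$lead, loci[[j]]$lead) > r2_min) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[rj] <- ri
      }
    }
  }
  groups <- split(seq_len(n), vapply(seq_len(n), find, integer(1)))
  merged <- lapply(groups, function(is) {
    leads <- vapply(loci[is], `[[`, character(1), "lead")
    members <- unique(unlist(lapply(loci[is], `[[`, "members")))
    structure(list(lead = sort(leads)[1], members = members,
                   r2_threshold = loci[[is[1]]]$r2_threshold),
              class = "locus")
  })
  names(merged) <- NULL
  # random assignment of members shared between non-merged loci
  all_members <- unlist(lapply(merged, `[[`, "members"))
  shared <- unique(all_members[duplicated(all_members)])
  if (length(shared) > 0) {
    rng <- local_rng(seed)
    on.exit(rng(), add = TRUE)
    for (s in shared) {
      holders <- which(vapply(merged, function(l) s %in% l$members, logical(1)))
      keep <- holders[sample.int(length(holders), 1)]
      for (h in setdiff(holders, keep)) {
        merged[[h]]$members <- setdiff(merged[[h]]$members, s)
      }
    }
  }
  merged
}

#' Remove SNPs near known loci
#'
#' Drops every SNP whose position lies within `radius_bp` (inclusive) of
#' any member of any known locus on the same chromosome.
#'
#' @param snps Summary-statistics `data.frame` (columns `id`, `chrom`,
#'   `pos`, ...).
#' @param known_members `data.frame` of known-locus member SNPs with
#'   columns `chrom` and `pos`.
#' @param radius_bp Exclusion radius (default 1 Mb).
#' @return The filtered `data.frame`.
#' @export
exclude_near_known <- function(snps, known_members, radius_bp = 1e6) {
  if (nrow(known_members) == 0 || nrow(snps) == 0) return(snps)
  drop <- rep(FALSE, nrow(snps))
  for (ch in unique(known_members$chrom)) {
    kp <- known_members$pos[known_members$chrom == ch]
    on_ch <- which(snps$chrom == ch)
    if (length(on_ch) == 0) next
    # nearest known member distance via sorted search
    kp <- sort(kp)
    pos <- snps$pos[on_ch]
    idx <- findInterval(pos, kp)
    d_lo <- ifelse(idx >= 1, pos - kp[pmax(idx, 1)], Inf)
    d_hi <- ifelse(idx < length(kp), kp[pmin(idx + 1, length(kp))] - pos, Inf)
    drop[on_ch] <- pmin(d_lo, d_hi) <= radius_bp
  }
  snps[!drop, , drop = FALSE]
}

#' Define independent sub-threshold loci by LD pruning
#'
#' Restricts to SNPs with `p < p_max`, sorts by ascending p-value
#' (ties broken by SNP id), and greedily keeps a SNP iff its r-squared
#' with every already-kept SNP is at most `r2_prune`. Each removed SNP
#' is attached to the kept SNP it was pruned against (the most
#' significant kept partner). The result is deterministic and invariant
#' to input row order.
#'
#' @param snps Summary-statistics `data.frame` (`id`, `chrom`, `pos`,
#'   `pvalue`).
#' @param panel An [ld_panel()].
#' @param p_max Sub-threshold cutoff (default 1e-4, strict `<`).
#' @param r2_prune Independence threshold (default 0.2; a pair with
#'   `r2 > 0.2` cannot both survive).
#' @return A `data.frame` with one row per locus: `representative`,
#'   `chrom`, `pos`, `pvalue` and a list-column `members` (pruned
#'   partners, including the representative).
#' @export
define_subthreshold_loci <- function(snps, panel, p_max = 1e-4,
                                     r2_prune = 0.2) {
  if (any(is.na(snps$pvalue))) stop("all SNPs must have p-values")
  cand <- snps[snps$pvalue < p_max, , drop = FALSE]
  if (nrow(cand) == 0) {
    return(data.frame(representative = character(0), chrom = character(0),
                      pos = integer(0), pvalue = numeric(0)))
  }
  cand <- cand[order(cand$pvalue, cand$id), , drop = FALSE]
  kept <- character(0)
  attached <- list()
  for (i in seq_len(nrow(cand))) {
    id <- cand$id[i]
    if (id %in% panel$ids) {
      conflicts <- intersect(kept, ld_partners(panel, id, r2_prune))
    } else {
      conflicts <- character(0)
    }
    if (length(conflicts) == 0) {
      kept <- c(kept, id)
      attached[[id]] <- id
    } else {
      # kept is in ascending-p order; the first conflict is the most
      # significant surviving partner
      rep_id <- conflicts[1]
      attached[[rep_id]] <- c(attached[[rep_id]], id)
    }
  }
  out <- cand[match(kept, cand$id), c("id", "chrom", "pos", "pvalue")]
  names(out)[1] <- "representative"
  rownames(out) <- NULL
  out$members <- I(unname(attached[kept]))
  out
}

#' Filter locus members to plausible causal candidates
#'
#' Retains a member SNP iff its -log10(p) is at least 80% of the
#' maximum -log10(p) among the locus members; equality retains (the
#' exclusion rule is "lower than").
#'
#' @param ids Character vector of member SNP ids.
#' @param pvalues Numeric p-values aligned with `ids`; `NA` allowed for
#'   partners without computed p-values (never retained).
#' @param fraction Fraction of the maximum -log10(p) required
#'   (default 0.8).
#' @return Character vector of retained ids.
#' @export
causal_candidate_filter <- function(ids, pvalues, fraction = 0.8) {
  if (all(is.na(pvalues))) stop("no member has a p-value")
  nlp <- -log10(pvalues)
  best <- max(nlp, na.rm = TRUE)
  ids[!is.na(nlp) & nlp >= fraction * best]
}

# Runs code under a temporary RNG state seeded with `seed`; returns a
# restore function.
local_rng <- function(seed) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  function() {
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }
}
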
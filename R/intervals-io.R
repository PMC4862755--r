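#' @importFrom GenomicRanges GRanges findOverlaps start end seqnames
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors queryHits subjectHits metadata metadata<- mcols mcols<-
NULL

# Coordinate conventions, used throughout the package:
#  * BED files on disk are 0-based half-open [start, end).
#  * In memory intervals are GRanges, 1-based inclusive [start, end].
#  * SNP positions in tables are 1-based; a SNP overlaps an interval iff
#    its single base lies inside it (no padding).

#' Build an annotation set from interval coordinates
#'
#' Constructs a sorted [GenomicRanges::GRanges] annotation set from
#' 0-based half-open (BED-convention) coordinates.
#'
#' @param chrom Character vector of chromosome names.
#' @param start,end Integer vectors: 0-based half-open interval bounds.
#' @param name Optional character vector of interval names.
#' @param label Optional label for the whole set (e.g. tissue + state),
#'   stored in the object metadata.
#' @return A sorted `GRanges`.
#' @export
annotation_set <- function(chrom, start, end, name = NULL, label = NULL) {
  if (any(!nzchar(chrom))) stop("chrom names must be non-empty")
  if (any(start < 0)) stop("start must be >= 0")
  if (any(end <= start)) stop("end must be > start for every interval")
  gr <- GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = start + 1L, end = end)
  )
  if (!is.null(name)) S4Vectors::mcols(gr)$name <- name
  gr <- GenomicRanges::sort(gr)
  if (!is.null(label)) S4Vectors::metadata(gr)$label <- label
  gr
}

#' Read a BED file of genomic intervals
#'
#' Parses a BED file (>= 3 tab-separated columns) into a sorted
#' `GRanges` annotation set. Track definition lines and `#` comments are
#' skipped. Coordinates are validated: an interval with `end <= start`
#' or a malformed line raises an error naming the offending line number.
#'
#' @param path Path to a BED file.
#' @param label Optional label stored in the result metadata.
#' @return A sorted `GRanges`; column 4, when present, becomes `name`.
#' @export
read_intervals <- function(path, label = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  keep <- !grepl("^(track|browser|#)", lines) & nzchar(trimws(lines))
  idx <- which(keep)
  if (length(idx) == 0) {
    return(annotation_set(character(), integer(), integer(), label = label))
  }
  fields <- strsplit(lines[idx], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3)) {
    bad <- idx[which(nf < 3)[1]]
    stop("malformed BED line ", bad, ": fewer than 3 tab-separated columns")
  }
  chrom <- vapply(fields, `[[`, character(1), 1L)
  start <- suppressWarnings(as.integer(vapply(fields, `[[`, character(1), 2L)))
  end <- suppressWarnings(as.integer(vapply(fields, `[[`, character(1), 3L)))
  if (anyNA(start) || anyNA(end)) {
    bad <- idx[which(is.na(start) | is.na(end))[1]]
    stop("malformed BED line ", bad, ": non-integer coordinates")
  }
  if (any(end <= start)) {
    bad <- idx[which(end <= start)[1]]
    stop("invalid interval at line ", bad, ": end <= start")
  }
  name <- if (any(nf >= 4)) {
    vapply(fields, function(f) if (length(f) >= 4) f[[4]] else NA_character_,
           character(1))
  } else NULL
  annotation_set(chrom, start, end, name = name, label = label)
}

#' Write intervals to a BED file
#'
#' Writes a `GRanges` to disk in BED convention (0-based half-open).
#'
#' @param gr A `GRanges`.
#' @param path Output path.
#' @export
write_intervals <- function(gr, path) {
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr)
  )
  nm <- S4Vectors::mcols(gr)$name
  if (!is.null(nm)) df$name <- nm
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a bedGraph signal track
#'
#' Parses a bedGraph file into a `GRanges` with a numeric `score`
#' column. Segments must be non-overlapping; positions not covered by
#' any segment have implicit value 0.
#'
#' @param path Path to a bedGraph file (chrom, start, end, value).
#' @return A sorted `GRanges` with `score`.
#' @export
read_signal_track <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  keep <- !grepl("^(track|browser|#)", lines) & nzchar(trimws(lines))
  idx <- which(keep)
  fields <- strsplit(lines[idx], "\t", fixed = TRUE)
  if (any(lengths(fields) < 4)) {
    bad <- idx[which(lengths(fields) < 4)[1]]
    stop("malformed bedGraph line ", bad, ": need 4 columns")
  }
  value <- as.numeric(vapply(fields, `[[`, character(1), 4L))
  if (any(!is.finite(value))) {
    bad <- idx[which(!is.finite(value))[1]]
    stop("non-finite signal value at line ", bad)
  }
  signal_track(
    chrom = vapply(fields, `[[`, character(1), 1L),
    start = as.integer(vapply(fields, `[[`, character(1), 2L)),
    end = as.integer(vapply(fields, `[[`, character(1), 3L)),
    value = value
  )
}

#' Build a signal track from segments
#'
#' Constructs a bedGraph-semantics step function as a `GRanges` with a
#' `score` column, from 0-based half-open segments. Overlapping segments
#' are rejected; uncovered positions have implicit value 0.
#'
#' @param chrom,start,end Segment coordinates (BED convention).
#' @param value Finite numeric values.
#' @return A sorted `GRanges` with `score`.
#' @export
signal_track <- function(chrom, start, end, value) {
  if (any(!is.finite(value))) stop("signal values must be finite")
  gr <- GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = start + 1L, end = end),
    score = value
  )
  gr <- GenomicRanges::sort(gr)
  ov <- GenomicRanges::findOverlaps(gr, drop.self = TRUE)
  if (length(ov) > 0) stop("signal track segments overlap")
  gr
}

#' Query an annotation set at a single SNP position
#'
#' Returns the intervals containing a 1-based SNP position.
#'
#' @param set A `GRanges` annotation set.
#' @param chrom Chromosome name.
#' @param pos 1-based position.
#' @return The subset of `set` containing the position (possibly empty).
#' @export
overlap_query <- function(set, chrom, pos) {
  set[snps_in_annotation_hits(set, chrom, pos)]
}

# index-level hits for one query position; disjoint seqlevel sets are a
# legitimate no-hit case, not worth a warning
snps_in_annotation_hits <- function(set, chrom, pos) {
  q <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, pos))
  S4Vectors::subjectHits(suppressWarnings(
    GenomicRanges::findOverlaps(q, set)))
}

#' Test which SNPs fall inside an annotation set
#'
#' Vectorized point-in-interval membership for 1-based SNP positions.
#'
#' @param set A `GRanges` annotation set.
#' @param chrom Character vector of chromosomes.
#' @param pos Integer vector of 1-based positions.
#' @return Logical vector, one element per SNP.
#' @export
snps_in_annotation <- function(set, chrom, pos) {
  if (length(pos) == 0) return(logical(0))
  q <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, pos))
  suppressWarnings(GenomicRanges::countOverlaps(q, set)) > 0
}

# ---- typed tables ---------------------------------------------------------

.schemas <- list(
  variants = c("id", "chrom", "pos", "maf", "on_array",
               "dist_to_nearest_gene", "n_genes_500kb"),
  summary_stats = c("id", "chrom", "pos", "pvalue"),
  expression = c("gene"),
  allele_counts = c("snp", "ref_reads", "alt_reads",
                    "ref_unique_pos", "alt_unique_pos"),
  fragends = c("position", "count")
)

#' Read a typed TSV table
#'
#' Reads one of the pipeline's tabular inputs and validates its field
#' invariants. Unknown extra columns are preserved.
#'
#' Schemas and required columns:
#' \describe{
#'   \item{variants}{id, chrom, pos, maf, on_array, dist_to_nearest_gene,
#'     n_genes_500kb; optional pvalue. maf must be in (0, 0.5].}
#'   \item{summary_stats}{id, chrom, pos, pvalue; empty p-value cells are
#'     allowed and read as `NA` (some LD partners have no computed p).}
#'   \item{expression}{gene plus one numeric column per tissue; values
#'     must be non-negative.}
#'   \item{allele_counts}{snp, ref_reads, alt_reads, ref_unique_pos,
#'     alt_unique_pos; unique-position counts cannot exceed read counts.}
#'   \item{fragends}{position, count; positions strictly increasing.}
#' }
#'
#' @param path Path to a tab-separated file with a header row.
#' @param schema One of `"variants"`, `"summary_stats"`, `"expression"`,
#'   `"allele_counts"`, `"fragends"`.
#' @return A validated `data.frame`.
#' @export
read_table <- function(path, schema = names(.schemas)) {
  schema <- match.arg(schema)
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          check.names = FALSE)
  validate_table(df, schema)
}

#' Validate a typed table against a schema
#'
#' @param df A `data.frame`.
#' @param schema Schema name (see [read_table()]).
#' @return The validated `data.frame` (invisibly unchanged).
#' @export
validate_table <- function(df, schema = names(.schemas)) {
  schema <- match.arg(schema)
  required <- .schemas[[schema]]
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    stop("missing required column(s) for schema '", schema, "': ",
         paste(missing_cols, collapse = ", "))
  }
  if (schema == "variants") {
    if (any(!is.finite(df$maf)) || any(df$maf <= 0) || any(df$maf > 0.5)) {
      stop("maf must lie in (0, 0.5]")
    }
    if (any(df$pos < 1)) stop("positions are 1-based and must be >= 1")
    if ("pvalue" %in% names(df)) check_pvalues(df$pvalue)
  } else if (schema == "summary_stats") {
    if (!is.numeric(df$pvalue)) stop("non-numeric p-value column")
    check_pvalues(df$pvalue)
    if (any(df$pos < 1)) stop("positions are 1-based and must be >= 1")
  } else if (schema == "expression") {
    tissue_cols <- setdiff(names(df), "gene")
    vals <- as.matrix(df[tissue_cols])
    if (!is.numeric(vals)) stop("expression values must be numeric")
    if (any(vals < 0, na.rm = TRUE)) stop("expression values must be >= 0")
  } else if (schema == "allele_counts") {
    counts <- c("ref_reads", "alt_reads", "ref_unique_pos", "alt_unique_pos")
    if (any(as.matrix(df[counts]) < 0)) stop("read counts must be >= 0")
    if (any(df$ref_unique_pos > df$ref_reads) ||
        any(df$alt_unique_pos > df$alt_reads)) {
      stop("unique-position counts cannot exceed read counts")
    }
  } else if (schema == "fragends") {
    if (any(diff(df$position) <= 0)) {
      stop("fragend positions must be strictly increasing")
    }
    if (any(df$count < 0)) stop("fragend counts must be >= 0")
  }
  df
}

check_pvalues <- function(p) {
  obs <- p[!is.na(p)]
  if (length(obs) > 0 && (any(obs <= 0) || any(obs > 1))) {
    stop("p-values must lie in (0, 1] (or be absent)")
  }
  invisible(TRUE)
}

#' Write a typed TSV table
#'
#' @param df A `data.frame`.
#' @param path Output path.
#' @export
write_table <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}
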
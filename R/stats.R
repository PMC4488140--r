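#' Read / write a genotype band table
#'
#' Tab-delimited long format: columns `marker`, `accession`, `alleles`
#' (comma-separated allele sizes in bp; blank = missing).
#'
#' @param path TSV path.
#' @return `read_genotype_table` returns a data.frame with columns
#'   `marker`, `accession`, `alleles` (character, comma-separated).
#' @export
read_genotype_table <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE,
                   colClasses = c("character", "character", "character"))
  stopifnot(identical(names(df), c("marker", "accession", "alleles")))
  df
}

#' @rdname read_genotype_table
#' @param table genotype data.frame.
#' @export
write_genotype_table <- function(table, path) {
  write.table(table[, c("marker", "accession", "alleles")], path,
              sep = "\t", quote = FALSE, row.names = FALSE, na = "")
  invisible(path)
}

# parse one cell's comma-separated allele sizes -> integer vector
parse_alleles <- function(x) {
  if (is.na(x) || !nzchar(x)) return(integer())
  as.integer(strsplit(x, ",", fixed = TRUE)[[1]])
}

#' Pooled allele frequencies for one marker
#'
#' Allele sizes are pooled across accessions; the frequency of each
#' distinct size is its count over the total number of observed alleles.
#'
#' @param table genotype table (long format, see
#'   [read_genotype_table()]).
#' @param marker_id marker to summarize.
#' @return named numeric vector of frequencies (names = allele sizes),
#'   summing to 1.
#' @export
allele_frequencies <- function(table, marker_id) {
  cells <- table$alleles[table$marker == marker_id]
  if (length(cells) == 0) stop("marker not present: ", marker_id)
  sizes <- unlist(lapply(cells, parse_alleles))
  if (length(sizes) == 0) stop("all cells missing for marker ", marker_id)
  if (any(sizes <= 0)) stop("allele sizes must be positive")
  tab <- table(sizes)
  stats::setNames(as.numeric(tab) / sum(tab), names(tab))
}

#' Polymorphism information content (PIC)
#'
#' PIC of a locus from its allele frequencies:
#' \deqn{PIC = 1 - \sum_i p_i^2 - \sum_{i<j} 2 p_i^2 p_j^2}
#' A simpler expected-heterozygosity variant
#' \eqn{1 - \sum_i p_i^2} is available via `method`.
#'
#' @param frequencies numeric vector of allele frequencies (must sum to
#'   1 within 1e-9).
#' @param method `"botstein"` (default) or `"expected_het"`.
#' @return PIC value in \[0, 1).
#' @examples
#' pic(c(0.5, 0.5))            # 0.375
#' pic(rep(0.25, 4))           # 0.703125
#' @export
pic <- function(frequencies, method = c("botstein", "expected_het")) {
  method <- match.arg(method)
  if (abs(sum(frequencies) - 1) > 1e-9)
    stop("allele frequencies must sum to 1")
  if (any(frequencies < 0)) stop("negative allele frequency")
  het <- 1 - sum(frequencies^2)
  if (method == "expected_het") return(het)
  p2 <- frequencies^2
  cross <- sum(p2)^2 - sum(p2^2)  # = sum_{i != j} p_i^2 p_j^2
  het - cross
}

#' Summarize a genotype table
#'
#' Per-marker allele counts, frequencies and PIC, plus a cohort summary:
#' markers tested / amplified (at least one scored accession) /
#' polymorphic (at least 2 alleles), total alleles over polymorphic
#' markers, mean alleles per polymorphic locus (truncated, not rounded,
#' to two decimals), PIC min/max/mean over polymorphic markers, and the
#' allele-count range.
#'
#' @param table genotype table (long format).
#' @param pic_method passed to [pic()].
#' @return list with `per_marker` (data.frame: marker_id, n_alleles,
#'   pic, polymorphic, amplified) and `cohort` (one-row data.frame).
#' @export
summarize_genotypes <- function(table, pic_method = "botstein") {
  stopifnot(nrow(table) > 0)
  ids <- unique(table$marker)
  per <- lapply(ids, function(id) {
    cells <- table$alleles[table$marker == id]
    sizes <- unlist(lapply(cells, parse_alleles))
    if (length(sizes) == 0)
      return(data.frame(marker_id = id, n_alleles = 0L, pic = NA_real_,
                        polymorphic = FALSE, amplified = FALSE))
    fr <- allele_frequencies(table, id)
    data.frame(marker_id = id, n_alleles = length(fr),
               pic = pic(fr, pic_method),
               polymorphic = length(fr) >= 2, amplified = TRUE,
               stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, c(per, list(make.row.names = FALSE)))
  poly <- per[per$polymorphic, , drop = FALSE]
  total_alleles <- sum(poly$n_alleles)
  mean_alleles <- if (nrow(poly)) trunc(100 * total_alleles / nrow(poly)) / 100
    else NA_real_
  cohort <- data.frame(
    markers_tested = length(ids),
    markers_amplified = sum(per$amplified),
    markers_polymorphic = nrow(poly),
    total_alleles = total_alleles,
    mean_alleles_per_locus = mean_alleles,
    min_alleles = if (nrow(poly)) min(poly$n_alleles) else NA_integer_,
    max_alleles = if (nrow(poly)) max(poly$n_alleles) else NA_integer_,
    pic_min = if (nrow(poly)) min(poly$pic) else NA_real_,
    pic_max = if (nrow(poly)) max(poly$pic) else NA_real_,
    pic_mean = if (nrow(poly)) mean(poly$pic) else NA_real_
  )
  list(per_marker = per, cohort = cohort)
}

#' PIC distribution histogram data
#'
#' @param per_marker the `per_marker` table from
#'   [summarize_genotypes()].
#' @param breaks bin boundaries in \[0, 1\].
#' @return data.frame of bins and marker counts.
#' @export
pic_histogram <- function(per_marker, breaks = seq(0, 1, 0.1)) {
  p <- per_marker$pic[per_marker$polymorphic]
  bins <- cut(p, breaks = breaks, include.lowest = TRUE)
  data.frame(bin_low = head(breaks, -1), bin_high = breaks[-1],
             count = as.integer(table(bins)))
}

#' Apply the marker pre-selection criteria
#'
#' Filters a fully evaluated marker table in order: (i) a single hit on
#' the reference genome (`map_status == "unique"`); (ii) transferability
#' (amplification in at least one other taxon,
#' `transferability_count >= 1`); (iii) in silico polymorphism
#' (`polymorphism == "polymorphic"`); (iv) elimination of TE-associated
#' markers. Criterion (v), priority for markers with functional
#' annotation, is a sort key (functional first), not a filter. The
#' per-criterion attrition report counts removals at each step.
#'
#' @param markers evaluated marker table with `map_status`,
#'   `transferability_count`, `polymorphism`, `te_associated`,
#'   `function_category` columns.
#' @return list: `markers` (filtered, functional-first), `attrition`
#'   (data.frame: criterion, removed, remaining).
#' @export
select_markers <- function(markers) {
  steps <- list(
    single_hit = function(df) df$map_status == "unique",
    transferable = function(df) !is.na(df$transferability_count) &
      df$transferability_count >= 1,
    polymorphic = function(df) !is.na(df$polymorphism) &
      df$polymorphism == "polymorphic",
    not_te_associated = function(df) !isTRUE_vec(df$te_associated)
  )
  attrition <- data.frame(criterion = character(), removed = integer(),
                          remaining = integer(), stringsAsFactors = FALSE)
  cur <- markers
  for (nm in names(steps)) {
    keep <- steps[[nm]](cur)
    keep[is.na(keep)] <- FALSE
    attrition <- rbind(attrition, data.frame(
      criterion = nm, removed = sum(!keep), remaining = sum(keep)))
    cur <- cur[keep, , drop = FALSE]
  }
  functional <- !is.na(cur$function_category) &
    !(cur$function_category %in% c("non_functional"))
  cur <- cur[order(!functional, cur$marker_id), , drop = FALSE]
  rownames(cur) <- NULL
  list(markers = cur, attrition = attrition)
}

isTRUE_vec <- function(x) !is.na(x) & x == TRUE
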
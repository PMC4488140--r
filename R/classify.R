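#' Tract-length class of an SSR
#'
#' Class I are long tracts (>= 20 bp), Class II short tracts (< 20 bp).
#' The 20 bp tract is assigned to Class I.
#'
#' @param tract_length integer vector of tract lengths in bp.
#' @return character vector, `"ClassI"` or `"ClassII"`.
#' @examples
#' length_class(c(12, 19, 20, 36))
#' @export
length_class <- function(tract_length) {
  ifelse(tract_length >= 20, "ClassI", "ClassII")
}

#' Base-composition class of a repeat motif
#'
#' AT-rich when more than half of the motif bases are A/T, GC-rich when
#' fewer than half, balanced at exactly half.
#'
#' @param motif character vector of repeat units over `A,C,G,T`.
#' @return character vector: `"AT-rich"`, `"GC-rich"` or `"balanced"`.
#' @examples
#' composition_class(c("AT", "CCG", "ACGT"))
#' @export
composition_class <- function(motif) {
  vapply(motif, function(m) {
    v <- s2c(m)
    at <- mean(v %in% c("A", "T"))
    if (at > 0.5) "AT-rich" else if (at < 0.5) "GC-rich" else "balanced"
  }, character(1), USE.NAMES = FALSE)
}

# expand compound loci into their member motifs for motif-level tallies
member_motifs <- function(loci) {
  if (nrow(loci) == 0) return(character())
  simple <- loci$motif[!loci$is_compound]
  comp <- loci$members[loci$is_compound]
  if (length(comp)) {
    parts <- unlist(strsplit(comp, ";", fixed = TRUE))
    comp_motifs <- sub(":.*$", "", parts)
  } else comp_motifs <- character()
  c(simple, comp_motifs)
}

#' Classify and tally one dataset's SSR loci
#'
#' Counts and integer-rounded percentages per repeat class (period),
#' canonical motif family, tract-length class and motif composition.
#' Motif-level axes (period, canonical motif, composition) count
#' compound-locus members individually; the length-class axis uses the
#' full tract of each locus (compound included). Percentages are taken
#' over this dataset's own totals.
#'
#' @param loci locus table.
#' @param dataset_tag dataset label.
#' @return an object of class `ssr_summary`: list with `dataset_tag`,
#'   `total_loci`, `by_period`, `by_canonical_motif`, `by_length_class`,
#'   `by_composition` (each a data.frame with `count` and `pct`).
#' @export
tabulate_dataset <- function(loci, dataset_tag = "other") {
  motifs <- member_motifs(loci)
  tab <- function(x, levels = NULL) {
    t <- if (is.null(levels)) table(x) else table(factor(x, levels = levels))
    data.frame(value = names(t), count = as.integer(t),
               pct = if (sum(t) == 0) rep(NA_real_, length(t)) else
                 pct_int(as.integer(t), sum(t)),
               row.names = NULL, stringsAsFactors = FALSE)
  }
  out <- list(
    dataset_tag = dataset_tag,
    total_loci = nrow(loci),
    by_period = tab(nchar(motifs), levels = as.character(2:6)),
    by_canonical_motif = tab(if (length(motifs)) canonical_motif(motifs)
                             else character()),
    by_length_class = tab(length_class(loci$tract_length),
                          levels = c("ClassI", "ClassII")),
    by_composition = tab(composition_class(motifs),
                         levels = c("AT-rich", "GC-rich", "balanced"))
  )
  class(out) <- "ssr_summary"
  out
}

#' @export
print.ssr_summary <- function(x, ...) {
  cat("SSR summary for dataset", x$dataset_tag,
      "-", x$total_loci, "loci\n")
  cat("By period:\n"); print(x$by_period)
  cat("By length class:\n"); print(x$by_length_class)
  cat("By composition:\n"); print(x$by_composition)
  invisible(x)
}

#' Combine per-dataset summaries into an overall column
#'
#' Each overall percentage is the unweighted arithmetic mean of the
#' per-dataset integer percentages, rounded half away from zero (not a
#' pooled-count percentage); overall densities combine the same way via
#' [combine_percent()]. With a single summary the overall column equals
#' that dataset.
#'
#' @param summaries list of `ssr_summary` objects (all with the same axis
#'   levels).
#' @return an `ssr_summary` with `dataset_tag = "overall"`; counts are
#'   summed, percentages are unweighted means of the inputs' integer
#'   percentages.
#' @export
combine_summaries <- function(summaries) {
  stopifnot(length(summaries) >= 1)
  stopifnot(all(vapply(summaries, inherits, logical(1), "ssr_summary")))
  combine_axis <- function(axis) {
    tabs <- lapply(summaries, `[[`, axis)
    values <- tabs[[1]]$value
    stopifnot(all(vapply(tabs, function(t) identical(t$value, values),
                         logical(1))))
    counts <- rowSums(vapply(tabs, `[[`, numeric(length(values)), "count"))
    pcts <- vapply(seq_along(values), function(i) {
      p <- vapply(tabs, function(t) t$pct[i], numeric(1))
      if (anyNA(p)) NA_real_ else combine_percent(p)
    }, numeric(1))
    data.frame(value = values, count = as.integer(counts), pct = pcts,
               stringsAsFactors = FALSE)
  }
  out <- list(
    dataset_tag = "overall",
    total_loci = sum(vapply(summaries, `[[`, numeric(1), "total_loci")),
    by_period = combine_axis("by_period"),
    by_canonical_motif = NULL,
    by_length_class = combine_axis("by_length_class"),
    by_composition = combine_axis("by_composition")
  )
  class(out) <- "ssr_summary"
  out
}

#' Serialize / parse an `ssr_summary` axis table as TSV
#'
#' @param summary an `ssr_summary`.
#' @param path output TSV path.
#' @return `write_summary_tsv` returns `path` invisibly;
#'   `read_summary_tsv` returns the `ssr_summary`.
#' @export
write_summary_tsv <- function(summary, path) {
  axes <- c("by_period", "by_canonical_motif", "by_length_class",
            "by_composition")
  rows <- do.call(rbind, lapply(axes, function(a) {
    t <- summary[[a]]
    if (is.null(t) || nrow(t) == 0) return(NULL)
    cbind(axis = a, t)
  }))
  header <- data.frame(axis = "total", value = summary$dataset_tag,
                       count = summary$total_loci, pct = NA_real_)
  write.table(rbind(header, rows), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname write_summary_tsv
#' @export
read_summary_tsv <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, colClasses = c(
    axis = "character", value = "character", count = "integer",
    pct = "numeric"))
  hd <- df[df$axis == "total", ]
  out <- list(dataset_tag = hd$value, total_loci = hd$count)
  for (a in c("by_period", "by_canonical_motif", "by_length_class",
              "by_composition")) {
    t <- df[df$axis == a, c("value", "count", "pct")]
    rownames(t) <- NULL
    out[[a]] <- if (nrow(t)) t else NULL
  }
  class(out) <- "ssr_summary"
  out
}
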
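#' Pipeline configuration
#'
#' Builds the configuration object consumed by every stage of the
#' pipeline. Defaults encode the marker-development protocol this package
#' implements: perfect di- to hexanucleotide repeats with minimum
#' 6/5/5/4/4 repeat units, 200 bp flanks per side, primers of 18--24 bp
#' with Tm 55--60 \eqn{\degree}C and GC 40--60\% amplifying 100--400 bp
#' products, electronic PCR budgets of at most 3 mismatches and 2 gaps
#' per primer with a 2 bp exact 3' anchor and a 5000 bp product cap, a
#' 10 bp amplicon-size polymorphism threshold, transposon-hit thresholds
#' of at least 65\% identity and E-value at most 1e-10, and at most 4
#' mismatches for mature-miRNA matching.
#'
#' @param min_repeat_units named integer vector mapping motif period
#'   ("2".."6") to the minimum number of repeat units.
#' @param flank_length flank length per side in bp.
#' @param primer_length_range,primer_tm_range,primer_gc_range,product_size_range
#'   length-2 numeric vectors of primer design constraints (bp, degrees C,
#'   percent, bp).
#' @param epcr_max_mismatches,epcr_max_gaps per-primer electronic PCR
#'   budgets.
#' @param epcr_anchor number of 3'-terminal primer bases that must match
#'   exactly.
#' @param epcr_max_product maximum in silico product size in bp.
#' @param polymorphism_threshold minimum amplicon-size difference in bp to
#'   call a marker polymorphic.
#' @param te_min_identity,te_max_evalue transposon association thresholds
#'   (percent identity, E-value).
#' @param mirna_max_mismatches maximum mismatches for a mature-miRNA match.
#' @param seed integer seed recorded in reports and used by simulators
#'   when no explicit seed is given.
#' @return a list of class `ssr_config`.
#' @examples
#' cfg <- ssr_config()
#' cfg$min_repeat_units
#' @export
ssr_config <- function(min_repeat_units = c(`2` = 6L, `3` = 5L, `4` = 5L,
                                            `5` = 4L, `6` = 4L),
                       flank_length = 200L,
                       primer_length_range = c(18L, 24L),
                       primer_tm_range = c(55, 60),
                       primer_gc_range = c(40, 60),
                       product_size_range = c(100L, 400L),
                       epcr_max_mismatches = 3L,
                       epcr_max_gaps = 2L,
                       epcr_anchor = 2L,
                       epcr_max_product = 5000L,
                       polymorphism_threshold = 10L,
                       te_min_identity = 65,
                       te_max_evalue = 1e-10,
                       mirna_max_mismatches = 4L,
                       seed = 1L) {
  cfg <- list(
    min_repeat_units = min_repeat_units,
    flank_length = as.integer(flank_length),
    primer_length_range = as.integer(primer_length_range),
    primer_tm_range = as.numeric(primer_tm_range),
    primer_gc_range = as.numeric(primer_gc_range),
    product_size_range = as.integer(product_size_range),
    epcr_max_mismatches = as.integer(epcr_max_mismatches),
    epcr_max_gaps = as.integer(epcr_max_gaps),
    epcr_anchor = as.integer(epcr_anchor),
    epcr_max_product = as.integer(epcr_max_product),
    polymorphism_threshold = as.integer(polymorphism_threshold),
    te_min_identity = as.numeric(te_min_identity),
    te_max_evalue = as.numeric(te_max_evalue),
    mirna_max_mismatches = as.integer(mirna_max_mismatches),
    seed = as.integer(seed)
  )
  validate_config(cfg)
  class(cfg) <- "ssr_config"
  cfg
}

validate_config <- function(cfg) {
  if (!all(as.character(2:6) %in% names(cfg$min_repeat_units)))
    stop("min_repeat_units must name periods 2..6")
  nums <- unlist(cfg[c("min_repeat_units", "flank_length",
                       "primer_length_range", "primer_tm_range",
                       "primer_gc_range", "product_size_range",
                       "polymorphism_threshold", "te_min_identity",
                       "te_max_evalue", "epcr_anchor", "epcr_max_product")])
  if (any(!is.finite(nums)) || any(nums <= 0))
    stop("all numeric configuration fields must be positive")
  if (cfg$epcr_max_mismatches < 0 || cfg$epcr_max_gaps < 0)
    stop("ePCR budgets must be non-negative")
  ranges <- c("primer_length_range", "primer_tm_range", "primer_gc_range",
              "product_size_range")
  for (r in ranges)
    if (cfg[[r]][1] > cfg[[r]][2]) stop(r, " must be increasing")
  invisible(cfg)
}

#' Read / write a pipeline configuration as YAML
#'
#' Flat-key YAML mirroring [ssr_config()]; unknown keys are rejected.
#'
#' @param path YAML file path.
#' @return `read_config` returns an `ssr_config`; `write_config` returns
#'   `path` invisibly.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  vals <- yaml::read_yaml(path)
  known <- names(formals(ssr_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
  if (!is.null(vals$min_repeat_units))
    vals$min_repeat_units <- unlist(vals$min_repeat_units)
  do.call(ssr_config, vals)
}

#' @rdname read_config
#' @param cfg an `ssr_config`.
#' @export
write_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "ssr_config"))
  out <- unclass(cfg)
  out$min_repeat_units <- as.list(out$min_repeat_units)
  yaml::write_yaml(out, path)
  invisible(path)
}
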
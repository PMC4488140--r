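#' Locate primer binding sites under mismatch/gap budgets
#'
#' Semi-global alignment of a primer against both strands of a subject
#' sequence. Candidate alignments are scored by cost = mismatches +
#' 2 * gaps; a site qualifies iff its minimum-cost alignment uses at
#' most `max_mismatches` substitutions AND at most `max_gaps` gaps
#' (budgets are per primer) AND its `anchor` 3'-terminal primer bases
#' match the subject exactly and contiguously. Overlapping candidate
#' alignments on a strand are collapsed to the minimum-cost one (ties
#' broken leftmost). `N` never matches.
#'
#' Plus-strand sites are occurrences of the primer sequence itself;
#' minus-strand sites are occurrences of its reverse complement (the
#' primer binds the plus strand as template).
#'
#' @param primer primer sequence (length >= 8).
#' @param subject subject DNA (character string or
#'   [Biostrings::DNAStringSet] element).
#' @param max_mismatches,max_gaps per-primer budgets.
#' @param anchor number of 3'-terminal bases that must match exactly.
#' @param strands which strands to search.
#' @return data.frame: `strand`, `start`, `end` (0-based half-open on
#'   the subject), `mismatches`, `gaps`, `cost`.
#' @export
find_binding_sites <- function(primer, subject, max_mismatches = 3L,
                               max_gaps = 2L, anchor = 2L,
                               strands = c("+", "-")) {
  stopifnot(nchar(primer) >= 8)
  tseq <- as.character(subject)[1]
  out <- list()
  if ("+" %in% strands)
    out[["+"]] <- sites_one_pattern(primer, tseq, max_mismatches,
                                    max_gaps, anchor, "+")
  if ("-" %in% strands)
    out[["-"]] <- sites_one_pattern(revcomp_dna(primer), tseq,
                                    max_mismatches, max_gaps, anchor, "-")
  res <- do.call(rbind, c(unname(out), list(make.row.names = FALSE)))
  if (is.null(res)) empty_sites() else res[order(res$start, res$strand), ,
                                           drop = FALSE]
}

empty_sites <- function() {
  data.frame(strand = character(), start = integer(), end = integer(),
             mismatches = integer(), gaps = integer(), cost = integer(),
             stringsAsFactors = FALSE)
}

# all qualifying sites of `pattern` (already oriented) on the plus strand
# of tseq; collapse overlapping candidates to minimum cost, leftmost.
sites_one_pattern <- function(pattern, tseq, MM, GG, anchor, strand_label) {
  m <- nchar(pattern)
  n <- nchar(tseq)
  if (n < m - GG) return(empty_sites())
  if (MM == 0L && GG == 0L) {
    hits <- Biostrings::matchPattern(pattern, Biostrings::DNAString(tseq))
    if (length(hits) == 0) return(empty_sites())
    return(data.frame(
      strand = strand_label,
      start = Biostrings::start(hits) - 1L,
      end = Biostrings::end(hits),
      mismatches = 0L, gaps = 0L, cost = 0L, stringsAsFactors = FALSE
    ))
  }
  p <- s2c(pattern)
  t <- s2c(tseq)
  eq <- lapply(seq_len(m), function(i) t == p[i] & t != "N")

  # A site is judged on the minimum-cost alignment ending at each text
  # position (cost = mismatches + 2 gaps), and qualifies only when that
  # optimal alignment fits the budgets: an alignment that squeezes under
  # the budgets by spending gaps to hide extra substitutions is never
  # preferred over the cheaper all-substitution alignment it shadows.
  # The mismatch dimension therefore runs to MM + 2*GG so the true
  # optimum is always visible to the comparison.
  MME <- MM + 2L * GG
  # f[[g+1]][[mm+1]] : logical over j = 0..n, pattern prefix i aligned
  # ending at text position j with <= mm mismatches, <= g gaps
  init <- rep(TRUE, n + 1L)
  prev <- lapply(0:GG, function(g) lapply(0:MME, function(mm) init))
  shift1 <- function(v) c(FALSE, v[seq_len(n)])
  for (i in seq_len(m)) {
    anchored <- i > m - anchor
    eqf <- c(FALSE, eq[[i]])
    cur <- lapply(0:GG, function(g) lapply(0:MME, function(mm) NULL))
    for (g in 0:GG) for (mm in 0:MME) {
      v <- shift1(prev[[g + 1L]][[mm + 1L]]) & eqf
      if (!anchored) {
        if (mm > 0)  # substitution
          v <- v | (shift1(prev[[g + 1L]][[mm]]) & !eqf)
        if (g > 0) {
          v <- v | prev[[g]][[mm + 1L]]            # primer base vs gap
          v <- v | shift1(cur[[g]][[mm + 1L]])     # subject base inserted
        }
      }
      cur[[g + 1L]][[mm + 1L]] <- v
    }
    prev <- cur
  }
  ends <- which(Reduce(`|`, lapply(prev, function(gl) Reduce(`|`, gl))))
  ends <- ends[ends > 1L] - 1L  # text end positions j >= 1 (1-based end)
  if (length(ends) == 0) return(empty_sites())
  sites <- lapply(ends, function(j) {
    # minimum cost over the (mm, g) grid, then the qualifying cell (if
    # any) among the minimum-cost cells, preferring fewer gaps
    cost_min <- Inf
    for (g in 0:GG) for (mm in 0:MME)
      if (prev[[g + 1L]][[mm + 1L]][j + 1L])
        cost_min <- min(cost_min, mm + 2L * g)
    best <- NULL
    for (g in 0:GG) for (mm in 0:MM)
      if (mm + 2L * g == cost_min && prev[[g + 1L]][[mm + 1L]][j + 1L] &&
          is.null(best))
        best <- list(mm = mm, g = g)
    if (is.null(best)) return(NULL)  # optimal alignment exceeds budgets
    tb <- traceback_start(p, t, j, best$mm, best$g, anchor)
    data.frame(strand = strand_label, start = tb$start, end = j,
               mismatches = tb$mm, gaps = tb$g, cost = tb$mm + 2L * tb$g,
               stringsAsFactors = FALSE)
  })
  sites <- sites[!vapply(sites, is.null, logical(1))]
  if (length(sites) == 0) return(empty_sites())
  sites <- do.call(rbind, c(sites, list(make.row.names = FALSE)))
  collapse_overlaps(sites)
}

# exact (mismatch, gap) counts and start position of the minimum-cost
# alignment of p ending at text position jend (1-based, inclusive)
traceback_start <- function(p, t, jend, mm_cap, g_cap, anchor) {
  m <- length(p)
  best <- NULL
  for (L in (m - g_cap):(m + g_cap)) {
    s <- jend - L + 1L
    if (L < 1 || s < 1) next
    tw <- t[s:jend]
    res <- global_budget_align(p, tw, mm_cap, g_cap, anchor)
    if (is.null(res)) next
    cost <- res$mm + 2L * res$g
    if (is.null(best) || cost < best$cost ||
        (cost == best$cost && s - 1L < best$start))
      best <- list(start = s - 1L, mm = res$mm, g = res$g, cost = cost)
  }
  best
}

# global alignment of pattern p vs text window tw with gap budget,
# minimizing mismatches per gap count; returns minimal-cost (mm, g)
# within budgets, or NULL. Anchor rows admit matches only.
global_budget_align <- function(p, tw, MM, GG, anchor) {
  m <- length(p)
  L <- length(tw)
  INF <- 1e9
  # M[[g+1]] is (m+1) x (L+1): min mismatches with <= g gaps
  M <- lapply(0:GG, function(g) matrix(INF, m + 1L, L + 1L))
  for (g in 0:GG) {
    M[[g + 1L]][1L, 1L] <- 0
    if (g > 0) {
      # leading gaps
      M[[g + 1L]][1L, seq_len(min(g, L)) + 1L] <- 0
      M[[g + 1L]][seq_len(min(g, m)) + 1L, 1L] <- 0
    }
  }
  for (g in 0:GG) for (i in seq_len(m)) {
    anchored <- i > m - anchor
    for (j in seq_len(L)) {
      sub <- if (p[i] == tw[j] && tw[j] != "N") M[[g + 1L]][i, j] else
        if (anchored) INF else M[[g + 1L]][i, j] + 1
      v <- sub
      if (g > 0 && !anchored) {
        v <- min(v, M[[g]][i, j + 1L])      # pattern base vs gap
        v <- min(v, M[[g]][i + 1L, j])      # text base inserted
      }
      M[[g + 1L]][i + 1L, j + 1L] <- v
    }
  }
  best <- NULL
  for (g in 0:GG) {
    mm <- M[[g + 1L]][m + 1L, L + 1L]
    if (mm <= MM) {
      cost <- mm + 2 * g
      if (is.null(best) || cost < best$cost)
        best <- list(mm = as.integer(mm), g = g, cost = cost)
    }
  }
  best
}

# keep the minimum-cost site in each set of mutually overlapping
# candidate alignments (ties -> leftmost)
collapse_overlaps <- function(sites) {
  if (nrow(sites) <= 1) return(sites)
  sites <- sites[order(sites$start, sites$end), , drop = FALSE]
  grp <- integer(nrow(sites))
  g <- 1L
  grp[1] <- g
  max_end <- sites$end[1]
  for (k in 2:nrow(sites)) {
    if (sites$start[k] >= max_end) g <- g + 1L
    grp[k] <- g
    max_end <- max(max_end, sites$end[k])
  }
  picked <- vapply(split(seq_len(nrow(sites)), grp), function(idx) {
    block <- sites[idx, , drop = FALSE]
    idx[order(block$cost, block$start)[1]]
  }, integer(1))
  out <- sites[sort(picked), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Electronic PCR of one primer pair against a sequence set
#'
#' Finds all convergent forward/reverse binding-site combinations on the
#' same sequence within the maximum product size, in both pair
#' orientations. Product size is the 5'-to-5' span.
#'
#' @param pair one designed marker row (needs `forward`, `reverse`).
#' @param genome target sequence set ([Biostrings::DNAStringSet] or
#'   named character vector).
#' @param config an [ssr_config()] supplying budgets and the product cap.
#' @param max_mismatches,max_gaps,anchor,max_product override the
#'   configured budgets.
#' @return data.frame of amplicons: `seq_id`, `start`, `end` (0-based
#'   half-open product span), `product_size`, `orientation`,
#'   `mismatches`, `gaps` (summed over the two primers).
#' @export
epcr <- function(pair, genome, config = ssr_config(),
                 max_mismatches = config$epcr_max_mismatches,
                 max_gaps = config$epcr_max_gaps,
                 anchor = config$epcr_anchor,
                 max_product = config$epcr_max_product) {
  stopifnot(!is.na(pair$forward), !is.na(pair$reverse))
  sv <- as_seqs(genome)
  ids <- names(sv)
  if (is.null(ids)) ids <- paste0("seq", seq_along(sv))
  out <- list()
  for (k in seq_along(sv)) {
    for (orient in c("FR", "RF")) {
      left <- if (orient == "FR") pair$forward else pair$reverse
      right <- if (orient == "FR") pair$reverse else pair$forward
      ls <- find_binding_sites(left, sv[[k]], max_mismatches, max_gaps,
                               anchor, strands = "+")
      if (nrow(ls) == 0) next
      rs <- find_binding_sites(right, sv[[k]], max_mismatches, max_gaps,
                               anchor, strands = "-")
      if (nrow(rs) == 0) next
      for (a in seq_len(nrow(ls))) for (b in seq_len(nrow(rs))) {
        if (rs$start[b] < ls$start[a]) next  # divergent
        size <- rs$end[b] - ls$start[a]
        if (size > max_product) next
        out[[length(out) + 1L]] <- data.frame(
          seq_id = ids[k], start = ls$start[a], end = rs$end[b],
          product_size = size, orientation = orient,
          mismatches = ls$mismatches[a] + rs$mismatches[b],
          gaps = ls$gaps[a] + rs$gaps[b], stringsAsFactors = FALSE
        )
      }
    }
  }
  if (length(out) == 0)
    return(data.frame(seq_id = character(), start = integer(),
                      end = integer(), product_size = integer(),
                      orientation = character(), mismatches = integer(),
                      gaps = integer(), stringsAsFactors = FALSE))
  res <- do.call(rbind, c(out, list(make.row.names = FALSE)))
  unique(res[order(res$seq_id, res$start), , drop = FALSE])
}

#' Physically map markers to a reference sequence set
#'
#' Runs [epcr()] per marker: `unique` iff exactly one amplicon
#' genome-wide, `multi` for more, `none` for no amplification. Compound
#' SSR markers are excluded (`excluded_compound`) and failed designs
#' carry `not_designed`. Only `unique` markers should proceed to the
#' transferability study.
#'
#' @param markers marker table.
#' @param genome reference sequence set.
#' @param config an [ssr_config()].
#' @return `markers` with added `map_status`, `chromosome` and
#'   `map_position` columns.
#' @export
physical_map <- function(markers, genome, config = ssr_config()) {
  markers$map_status <- NA_character_
  markers$chromosome <- NA_character_
  markers$map_position <- NA_integer_
  for (i in seq_len(nrow(markers))) {
    if (isTRUE(markers$is_compound[i])) {
      markers$map_status[i] <- "excluded_compound"
      next
    }
    if (is.na(markers$forward[i])) {
      markers$map_status[i] <- "not_designed"
      next
    }
    hits <- epcr(markers[i, ], genome, config)
    markers$map_status[i] <-
      if (nrow(hits) == 0) "none" else if (nrow(hits) == 1) "unique" else
        "multi"
    if (nrow(hits) == 1) {
      markers$chromosome[i] <- hits$seq_id
      markers$map_position[i] <- hits$start
    }
  }
  markers
}

#' Classify a marker's amplicon-size variation
#'
#' Polymorphic iff any observed amplicon size differs from the expected
#' size by at least `threshold` bp (default 10); smaller differences are
#' monomorphic.
#'
#' @param expected expected product size in bp.
#' @param observed vector of observed amplicon sizes (non-empty).
#' @param threshold minimum absolute size difference in bp.
#' @return `"polymorphic"` or `"monomorphic"`.
#' @examples
#' classify_polymorphism(200, c(210))  # polymorphic (boundary)
#' @export
classify_polymorphism <- function(expected, observed, threshold = 10L) {
  if (length(observed) == 0) stop("empty observation set")
  if (any(abs(observed - expected) >= threshold)) "polymorphic" else
    "monomorphic"
}

#' Cross-taxon transferability matrix
#'
#' For each (marker, genome) cell runs [epcr()] and classifies the
#' outcome: `no_hit`, `multi_locus` (more than one amplicon),
#' `monomorphic` or `polymorphic` (single amplicon, size compared with
#' the marker's expected product). Per-genome transferability is the
#' percentage of markers with at least one amplicon.
#'
#' @param markers marker table (normally the `unique`-mapped subset).
#' @param genomes named list of target sequence sets.
#' @param config an [ssr_config()].
#' @return list: `matrix` (data.frame, markers x genomes),
#'   `per_genome` (data.frame: genome, pct_transferable,
#'   pct_polymorphic).
#' @export
transferability_matrix <- function(markers, genomes, config = ssr_config()) {
  stopifnot(!is.null(names(genomes)))
  cells <- matrix(NA_character_, nrow(markers), length(genomes),
                  dimnames = list(markers$marker_id, names(genomes)))
  for (i in seq_len(nrow(markers))) {
    for (gname in names(genomes)) {
      hits <- epcr(markers[i, ], genomes[[gname]], config)
      cells[i, gname] <-
        if (nrow(hits) == 0) "no_hit"
        else if (nrow(hits) > 1) "multi_locus"
        else classify_polymorphism(markers$expected_product[i],
                                   hits$product_size,
                                   config$polymorphism_threshold)
    }
  }
  per_genome <- data.frame(
    genome = names(genomes),
    pct_transferable = vapply(colnames(cells), function(g)
      100 * mean(cells[, g] != "no_hit"), numeric(1)),
    pct_polymorphic = vapply(colnames(cells), function(g)
      100 * mean(cells[, g] == "polymorphic"), numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE
  )
  list(matrix = as.data.frame(cells, stringsAsFactors = FALSE),
       per_genome = per_genome)
}
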
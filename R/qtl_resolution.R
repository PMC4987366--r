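# Conversion of cross-location candidate effects into named QTLs via
# introgression overlap and IL-vs-IL contrast tests: overlapping ILs whose
# means do not differ support one QTL in the shared region; ILs whose
# means differ support distinct QTLs outside the shared region.

#' Group candidate effects by trait and chromosome
#'
#' Places every candidate (line, trait) effect into one group per
#' (trait, chromosome) for which the line carries introgression segments,
#' together with the pairwise physical-overlap matrix of the members'
#' segments. A line with segments on several chromosomes cannot be
#' localized by the IL design: it joins every compatible group and is
#' flagged ambiguous.
#'
#' @param candidates a [consistency_filter()] result.
#' @param library an [il_library()].
#' @return List of `overlap_group` objects (fields `trait`, `chrom`,
#'   `members` data.frame with `line`, `mean_pct_diff`, `n_locations`,
#'   `locations`, `ambiguous`; and `overlap`, a logical member matrix).
#' @export
build_overlap_groups <- function(candidates, library) {
  stopifnot(inherits(library, "il_library"))
  cand <- as.data.frame(candidates)
  if (nrow(cand) == 0L) return(list())
  known <- il_lines(library)
  bad <- setdiff(cand$line, known)
  if (length(bad) > 0L)
    stop("candidate line(s) absent from library: ",
         paste(bad, collapse = ", "))
  chrom_of <- lapply(cand$line, function(ln)
    unique(library$segments$chrom[library$segments$line == ln]))
  rows <- do.call(rbind, lapply(seq_len(nrow(cand)), function(i) {
    data.frame(idx = i, chrom = chrom_of[[i]],
               ambiguous = length(chrom_of[[i]]) > 1L)
  }))
  groups <- list()
  for (key in split(rows, list(cand$trait[rows$idx], rows$chrom),
                    drop = TRUE)) {
    if (nrow(key) == 0L) next
    members <- cand[key$idx, c("line", "trait", "mean_pct_diff",
                               "n_locations", "locations", "sign")]
    members$ambiguous <- key$ambiguous
    rownames(members) <- NULL
    chrom <- key$chrom[1L]
    ivs <- lapply(members$line, line_iv, library = library, chrom = chrom)
    k <- nrow(members)
    ov <- matrix(FALSE, k, k, dimnames = list(members$line, members$line))
    if (k > 1L) for (i in 1:(k - 1)) for (j in (i + 1):k) {
      ov[i, j] <- ov[j, i] <- iv_overlaps(ivs[[i]], ivs[[j]])
    }
    diag(ov) <- TRUE
    g <- list(trait = members$trait[1L], chrom = chrom, members = members,
              overlap = ov)
    class(g) <- "overlap_group"
    groups[[length(groups) + 1L]] <- g
  }
  ord <- order(vapply(groups, function(g) g$trait, character(1)),
               vapply(groups, function(g)
                 match(g$chrom, library$genome$chrom), numeric(1)))
  groups[ord]
}

#' IL-vs-IL contrast test
#'
#' Tests equality of two ILs' block-adjusted means for one trait, pooled
#' over the locations where both lines were phenotyped (or a supplied
#' subset, e.g. the qualifying locations of both candidates). Per-location
#' differences are combined by inverse-variance weighting using each
#' location fit's error variance, with Welch–Satterthwaite degrees of
#' freedom; the p-value is two-sided.
#'
#' @param table a [phenotype_table()].
#' @param trait trait code.
#' @param line_a,line_b IL identifiers.
#' @param locations locations to pool over (default: all shared locations
#'   with data for both lines).
#' @param alpha significance level for the flag (default 0.05).
#' @param block_adjust passed to [fit_location_model()].
#' @return A `contrast_result` list: `line_a`, `line_b`, `trait`,
#'   `estimate`, `se`, `df`, `p`, `significant`, `locations`.
#' @export
contrast_test <- function(table, trait, line_a, line_b, locations = NULL,
                          alpha = 0.05, block_adjust = TRUE) {
  stopifnot(inherits(table, "phenotype_table"))
  d <- as.data.frame(table)
  d <- d[d$trait == trait & !is.na(d$value), ]
  has <- function(ln) unique(d$location[d$line == ln])
  shared <- intersect(has(line_a), has(line_b))
  if (!is.null(locations)) shared <- intersect(shared, locations)
  if (length(shared) == 0L)
    stop("no shared location with data for ", line_a, " and ", line_b)
  est <- var_l <- df_l <- numeric(0)
  for (loc in sort(shared)) {
    fit <- fit_location_model(table, trait, loc, block_adjust = block_adjust)
    if (!all(c(line_a, line_b) %in% names(fit$diff))) next
    i <- match(line_a, colnames(fit$corr))
    j <- match(line_b, colnames(fit$corr))
    dl <- fit$diff[[line_a]] - fit$diff[[line_b]]
    vl <- fit$se[i]^2 + fit$se[j]^2 -
      2 * fit$corr[i, j] * fit$se[i] * fit$se[j]
    est <- c(est, dl); var_l <- c(var_l, vl); df_l <- c(df_l, fit$df)
  }
  if (length(est) == 0L)
    stop("no shared location with fitted comparisons for ", line_a,
         " and ", line_b)
  w <- 1 / var_l
  estimate <- sum(w * est) / sum(w)
  v_terms <- w^2 * var_l / sum(w)^2        # = contributions to Var(estimate)
  v_hat <- sum(v_terms)                    # = 1 / sum(w)
  df <- v_hat^2 / sum(v_terms^2 / df_l)    # Welch–Satterthwaite
  tt <- estimate / sqrt(v_hat)
  p <- 2 * stats::pt(-abs(tt), df)
  out <- list(line_a = line_a, line_b = line_b, trait = trait,
              estimate = estimate, se = sqrt(v_hat), df = df, p = p,
              significant = p < alpha, locations = sort(shared))
  class(out) <- "contrast_result"
  out
}

# connected components of a logical adjacency matrix (BFS)
components_of <- function(adj) {
  k <- nrow(adj)
  comp <- rep(NA_integer_, k)
  cur <- 0L
  for (s in seq_len(k)) {
    if (!is.na(comp[s])) next
    cur <- cur + 1L
    queue <- s
    while (length(queue) > 0L) {
      v <- queue[[1L]]; queue <- queue[-1L]
      if (!is.na(comp[v])) next
      comp[v] <- cur
      queue <- c(queue, which(adj[v, ] & is.na(comp)))
    }
  }
  comp
}

#' Resolve an overlap group into QTL records
#'
#' Implements the merge-or-split rule on one (trait, chromosome) group:
#' an edge joins two members whose introgressions overlap physically and
#' whose contrast is NOT significant; each connected component of that
#' graph becomes one QTL. A component's physical interval is the
#' intersection of its members' segments (their shared region) when
#' non-empty, otherwise their union (flagged). When two overlapping
#' members end up in different components (significant contrast), the
#' shared overlap is removed from each component's interval, so two
#' distinct QTLs flank the boundary; if the subtraction would empty an
#' interval the full introgression is kept and flagged. Non-overlapping
#' members always yield separate QTLs. Serials are assigned by ascending
#' physical start within the (trait, chromosome).
#'
#' @param group an `overlap_group` from [build_overlap_groups()].
#' @param contrasts list of [contrast_test()] results covering every
#'   overlapping member pair (missing pairs are an error).
#' @param library an [il_library()].
#' @param alpha significance level for contrasts (default 0.05).
#' @return List of `qtl_record` objects; see [name_qtls()] for naming and
#'   [qtl_table()] for a tabular view. Every record's interval pieces are
#'   asserted to lie within the union of its supporting lines'
#'   introgressions.
#' @export
resolve_qtls <- function(group, contrasts = list(), library, alpha = 0.05) {
  stopifnot(inherits(group, "overlap_group"),
            inherits(library, "il_library"))
  mem <- group$members
  k <- nrow(mem)
  ivs <- lapply(mem$line, line_iv, library = library, chrom = group$chrom)
  names(ivs) <- mem$line
  # contrast lookup by unordered pair
  ckey <- function(a, b) paste(sort(c(a, b)), collapse = "\r")
  cmap <- new.env(parent = emptyenv())
  for (ct in contrasts) {
    if (!identical(ct$trait, group$trait)) next
    assign(ckey(ct$line_a, ct$line_b), isTRUE(ct$significant), envir = cmap)
  }
  adj <- diag(k) == 1
  sig_pair <- matrix(FALSE, k, k)
  missing_pairs <- character(0)
  if (k > 1L) for (i in 1:(k - 1)) for (j in (i + 1):k) {
    if (!group$overlap[i, j]) next
    key <- ckey(mem$line[i], mem$line[j])
    if (!exists(key, envir = cmap)) {
      missing_pairs <- c(missing_pairs,
                         paste(mem$line[i], mem$line[j], sep = " / "))
      next
    }
    s <- get(key, envir = cmap)
    sig_pair[i, j] <- sig_pair[j, i] <- s
    if (!s) adj[i, j] <- adj[j, i] <- TRUE
  }
  if (length(missing_pairs) > 0L)
    stop("missing contrast for overlapping pair(s): ",
         paste(missing_pairs, collapse = "; "))
  comp <- components_of(adj)
  records <- list()
  for (ci in sort(unique(comp))) {
    members <- which(comp == ci)
    interval <- Reduce(iv_intersect, ivs[members])
    flags <- character(0)
    if (iv_length(interval) == 0) {
      interval <- Reduce(iv_union, ivs[members])
      flags <- c(flags, "empty_intersection_used_union")
    }
    # subtract regions shared with significantly-different members of
    # other components
    shared_other <- iv()
    for (i in members) for (j in seq_len(k)) {
      if (comp[j] == ci) next
      if (group$overlap[i, j] && sig_pair[i, j])
        shared_other <- iv_union(shared_other,
                                 iv_intersect(ivs[[i]], ivs[[j]]))
    }
    if (iv_length(shared_other) > 0) {
      trimmed <- iv_setdiff(interval, shared_other)
      if (iv_length(trimmed) > 0) {
        interval <- trimmed
      } else {
        flags <- c(flags, "split_would_empty_interval")
      }
    }
    support_union <- Reduce(iv_union, ivs[members])
    stopifnot(iv_contains(support_union, interval))  # hard invariant
    if (any(mem$ambiguous[members]))
      flags <- c(flags, "ambiguous_multi_chromosome_support")
    # genetic interval: range over supporting segments carrying cM coords
    segs <- library$segments[library$segments$line %in% mem$line[members] &
                               library$segments$chrom == group$chrom, ]
    cm <- c(NA_real_, NA_real_)
    if (any(!is.na(segs$start_cm)))
      cm <- c(min(segs$start_cm, na.rm = TRUE),
              max(segs$end_cm, na.rm = TRUE))
    rec <- list(name = NA_character_, trait = group$trait,
                chrom = group$chrom, interval = interval,
                mb_start = iv_span(interval)[1L],
                mb_end = iv_span(interval)[2L],
                cm_start = cm[1L], cm_end = cm[2L],
                n_locations = max(mem$n_locations[members]),
                pct_diff = mean(mem$mean_pct_diff[members]),
                lines = mem$line[members], flags = flags)
    class(rec) <- "qtl_record"
    records[[length(records) + 1L]] <- rec
  }
  ord <- order(vapply(records, function(r) r$mb_start, numeric(1)))
  records[ord]
}

#' Assign QTL names
#'
#' Names each record `<trait prefix><chromosome>.<serial>` (e.g. `fw2.1`),
#' with the trait prefix from [trait_catalog()] and serials assigned by
#' ascending physical start within each (trait, chromosome), restarting
#' at 1 per chromosome. Input order does not affect the result.
#'
#' @param records list of `qtl_record` objects (from [resolve_qtls()],
#'   possibly concatenated across groups).
#' @return The records, named, in canonical (trait, chromosome, start)
#'   order.
#' @export
name_qtls <- function(records) {
  if (length(records) == 0L) return(records)
  cat_tab <- trait_catalog()
  key <- vapply(records, function(r)
    sprintf("%s\r%s\r%017.6f", r$trait, r$chrom, r$mb_start), character(1))
  if (anyDuplicated(vapply(records, function(r)
    sprintf("%s\r%s\r%.9f\r%.9f", r$trait, r$chrom, r$mb_start, r$mb_end),
    character(1))))
    stop("duplicate (trait, chromosome, interval) records")
  records <- records[order(key)]
  serial <- stats::ave(seq_along(records),
                       vapply(records, function(r)
                         paste(r$trait, r$chrom), character(1)),
                       FUN = seq_along)
  for (i in seq_along(records)) {
    r <- records[[i]]
    pre <- cat_tab$qtl_prefix[match(r$trait, cat_tab$code)]
    if (is.na(pre)) pre <- tolower(r$trait)
    records[[i]]$name <- paste0(pre, r$chrom, ".", serial[i])
  }
  records
}

#' Tabular view of QTL records
#'
#' @param records list of `qtl_record` objects.
#' @return data.frame with one row per QTL (interval hull in Mb, genetic
#'   interval in cM when available, supporting lines semicolon-joined,
#'   mean percent difference from the control rounded to integer percent
#'   for reporting).
#' @export
qtl_table <- function(records) {
  if (length(records) == 0L)
    return(data.frame(qtl = character(), trait = character(),
                      chrom = character(), cm_start = numeric(),
                      cm_end = numeric(), mb_start = numeric(),
                      mb_end = numeric(), n_locations = integer(),
                      pct_diff = numeric(), lines = character(),
                      flags = character()))
  do.call(rbind, lapply(records, function(r) data.frame(
    qtl = r$name, trait = r$trait, chrom = r$chrom,
    cm_start = r$cm_start, cm_end = r$cm_end,
    mb_start = r$mb_start, mb_end = r$mb_end,
    n_locations = r$n_locations, pct_diff = round(r$pct_diff),
    lines = paste(r$lines, collapse = ";"),
    flags = paste(r$flags, collapse = ";"))))
}

#' Mean percent difference of a candidate over its qualifying locations
#'
#' @param candidate one row of a [consistency_filter()] result.
#' @param screen_results the `comparison_results` the candidate came from.
#' @return Mean of the per-location percent differences over the
#'   candidate's qualifying locations (unrounded; reports round to integer
#'   percent).
#' @export
effect_summary <- function(candidate, screen_results) {
  locs <- strsplit(candidate$locations, ";", fixed = TRUE)[[1L]]
  res <- as.data.frame(screen_results)
  res <- res[res$line == candidate$line & res$trait == candidate$trait &
               res$location %in% locs, ]
  mean(res$pct_diff)
}
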
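#' Per-residue B-factor profile of a chain
#'
#' Aggregates isotropic temperature factors per polymer residue, the raw
#' flexibility trace plotted along the sequence when comparing crystal
#' structures.  Residues lacking every atom of the aggregation set are skipped
#' and counted.
#'
#' @param model a `StructureModel`.
#' @param chain_id chain identifier.
#' @param aggregation `"mainchain-mean"` (default; mean over N, CA, C, O),
#'   `"all-atom-mean"`, or `"CA-only"`.
#' @return A `BFactorProfile`: data.frame with columns `resno`, `icode`,
#'   `label`, `value` (Angstrom^2), with attributes `aggregation`, `chain_id`,
#'   `n_skipped`.
#' @export
residue_bfactor_profile <- function(model, chain_id,
                                    aggregation = c("mainchain-mean",
                                                    "all-atom-mean", "CA-only")) {
  aggregation <- match.arg(aggregation)
  ch <- get_chain(model, chain_id, polymer_only = TRUE)
  if (nrow(ch) == 0L) {
    stop(sprintf("residue_bfactor_profile: chain %s has no polymer atoms", chain_id),
         call. = FALSE)
  }
  sel <- switch(aggregation,
                "mainchain-mean" = ch$atom %in% MAINCHAIN_ATOMS,
                "all-atom-mean" = ch$element != "H",
                "CA-only" = ch$atom == "CA")
  keys_all <- unique(residue_key(ch))
  sub <- ch[sel, , drop = FALSE]
  if (nrow(sub) == 0L) {
    stop("residue_bfactor_profile: no atoms match the aggregation set", call. = FALSE)
  }
  key <- residue_key(sub)
  agg <- tapply(sub$b, key, mean)
  first <- sub[!duplicated(key), , drop = FALSE]
  ord <- order(first$resno, first$icode)
  first <- first[ord, , drop = FALSE]
  values <- as.numeric(agg[residue_key(first)])
  out <- data.frame(resno = first$resno, icode = first$icode,
                    label = residue_label(first$resname, first$resno, first$icode),
                    value = values, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(out, aggregation = aggregation, chain_id = chain_id,
            n_skipped = length(keys_all) - nrow(out),
            class = c("BFactorProfile", "data.frame"))
}

#' Mean B-factor over all protein atoms of a structure
#'
#' Whole-structure average temperature factor over polymer heavy atoms (the
#' "average B-factor, protein" statistic of refinement tables).
#'
#' @param model a `StructureModel`.
#' @param kind atom kinds to average over (default polymer).
#' @return mean B in Angstrom^2.
#' @export
mean_structure_bfactor <- function(model, kind = "polymer") {
  stopifnot(inherits(model, "StructureModel"))
  a <- model$atoms
  sel <- a$kind %in% kind & a$element != "H"
  if (!any(sel)) stop("mean_structure_bfactor: no atoms of requested kind", call. = FALSE)
  mean(a$b[sel])
}

#' Max-normalize a B-factor profile
#'
#' Divides every per-residue value by the profile maximum, so structures
#' refined on different absolute B scales can be overlaid ("normalized to the
#' highest value in each data set").  The maximum used is recorded as the
#' `normalizer` attribute; the operation is idempotent.
#'
#' @param profile a `BFactorProfile` (or `NormalizedProfile`).
#' @return A `NormalizedProfile` with values in `[0, 1]` and max exactly 1.
#' @export
normalize_profile <- function(profile) {
  stopifnot(is.data.frame(profile), nrow(profile) > 0L)
  m <- max(profile$value)
  if (m <= 0) stop("normalize_profile: profile maximum must be positive", call. = FALSE)
  out <- profile
  out$value <- out$value / m
  structure(as.data.frame(out),
            normalizer = m,
            aggregation = attr(profile, "aggregation"),
            chain_id = attr(profile, "chain_id"),
            class = c("NormalizedProfile", "data.frame"))
}

#' Smooth a profile with a centered moving mean
#'
#' Optional light smoothing for plotting; not applied by default anywhere.
#'
#' @param profile a profile data.frame with a `value` column.
#' @param window odd window width in residues.
#' @return The profile with smoothed values (ends use shrinking windows).
#' @export
smooth_profile <- function(profile, window = 3L) {
  stopifnot(window >= 1L, window %% 2L == 1L)
  v <- profile$value
  half <- (window - 1L) %/% 2L
  n <- length(v)
  sm <- vapply(seq_len(n), function(i) {
    mean(v[max(1L, i - half):min(n, i + half)])
  }, numeric(1))
  profile$value <- sm
  profile
}

#' Compare two normalized flexibility profiles
#'
#' Joins two normalized profiles on residue labels, takes the pointwise
#' difference (X minus Y), and flags maximal runs of at least `min_run`
#' consecutive shared residues whose absolute difference meets `threshold` --
#' the "differential flexibility region" call used when a variant structure
#' gains mobility relative to the wild-type.
#'
#' @param prof_x,prof_y `NormalizedProfile` objects sharing >= 10 residues.
#' @param threshold minimum absolute normalized-B difference (default 0.10).
#' @param min_run minimum run length in residues (default 5).
#' @return A `FlexibilityComparison`: data.frame with columns `resno`, `icode`,
#'   `label`, `value_x`, `value_y`, `difference`; attribute `regions` is a
#'   data.frame (`start_resno`, `end_resno`, `start_label`, `end_label`,
#'   `n_residues`, `mean_difference`, `mean_abs_difference`); attributes
#'   `threshold` and `min_run` echo the call.
#' @export
compare_flexibility <- function(prof_x, prof_y, threshold = 0.10, min_run = 5L) {
  stopifnot(threshold > 0, min_run >= 1L)
  key_x <- paste(prof_x$resno, prof_x$icode, sep = "|")
  key_y <- paste(prof_y$resno, prof_y$icode, sep = "|")
  common <- intersect(key_x, key_y)
  if (length(common) < 10L) {
    stop("compare_flexibility: profiles share fewer than 10 residues", call. = FALSE)
  }
  ix <- match(common, key_x)
  iy <- match(common, key_y)
  df <- data.frame(resno = prof_x$resno[ix], icode = prof_x$icode[ix],
                   label = prof_x$label[ix],
                   value_x = prof_x$value[ix], value_y = prof_y$value[iy],
                   stringsAsFactors = FALSE)
  df <- df[order(df$resno, df$icode), , drop = FALSE]
  rownames(df) <- NULL
  df$difference <- df$value_x - df$value_y

  hit <- abs(df$difference) >= threshold
  runs <- rle(hit)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  keep <- runs$values & runs$lengths >= min_run
  regions <- data.frame(start_resno = df$resno[starts[keep]],
                        end_resno = df$resno[ends[keep]],
                        start_label = df$label[starts[keep]],
                        end_label = df$label[ends[keep]],
                        n_residues = runs$lengths[keep],
                        mean_difference = vapply(which(keep), function(i) {
                          mean(df$difference[starts[i]:ends[i]])
                        }, numeric(1)),
                        mean_abs_difference = vapply(which(keep), function(i) {
                          mean(abs(df$difference[starts[i]:ends[i]]))
                        }, numeric(1)),
                        stringsAsFactors = FALSE)
  structure(df, regions = regions, threshold = threshold, min_run = min_run,
            class = c("FlexibilityComparison", "data.frame"))
}

#' Percentile-mapped worm radii from a normalized profile
#'
#' Maps per-residue normalized B-factors to rendering radii the way B-factor
#' "worm" figures are drawn: values at or below the 5th percentile map to
#' 0.3 Angstrom, at or above the 95th to 1.25 Angstrom, linear in between.
#' Degenerate (constant) profiles map everything to the 0.80 mid-score.
#'
#' @param profile a `NormalizedProfile` (any per-residue profile works).
#' @param lo,hi radius bounds in Angstrom.
#' @return A `WormScore`: data.frame with columns `resno`, `icode`, `label`,
#'   `value`, `radius`; attribute `scale` records the percentile band.
#' @export
worm_scores <- function(profile, lo = 0.3, hi = 1.25) {
  stopifnot(is.data.frame(profile), nrow(profile) > 0L, lo < hi)
  v <- profile$value
  p <- stats::quantile(v, c(0.05, 0.95), names = FALSE, type = 7)
  if (p[2] - p[1] <= .Machine$double.eps^0.5) {
    radius <- rep(0.80, length(v))
  } else {
    radius <- lo + (v - p[1]) / (p[2] - p[1]) * (hi - lo)
    radius <- pmin(hi, pmax(lo, radius))
  }
  out <- data.frame(resno = profile$resno, icode = profile$icode,
                    label = profile$label, value = v, radius = radius,
                    stringsAsFactors = FALSE)
  structure(out, scale = c(lo = lo, hi = hi, p05 = p[1], p95 = p[2]),
            class = c("WormScore", "data.frame"))
}

#' Write a profile or comparison as TSV
#' @param x a profile / comparison data.frame.
#' @param path output path.
#' @return The path, invisibly.
#' @export
write_profile_tsv <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write flagged flexibility regions as BED-like text
#'
#' Three columns (chain label, start residue, end residue), residue numbers
#' 1-based and inclusive, stated in a header line.
#'
#' @param comparison a `FlexibilityComparison`.
#' @param path output path.
#' @param name region-set label placed in column 1.
#' @return The path, invisibly.
#' @export
write_regions_bed <- function(comparison, path, name = "flex_region") {
  regions <- attr(comparison, "regions")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# residue intervals are author-numbered, 1-based, inclusive", con)
  if (nrow(regions)) {
    utils::write.table(data.frame(name, regions$start_resno, regions$end_resno),
                       con, sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = FALSE)
  }
  invisible(path)
}
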
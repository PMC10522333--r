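#' Relative polar position of a receiver around an emitter
#'
#' Expresses the receiver snout in a polar frame centred on the emitter
#' snout: radius = snout-snout distance; angle = unsigned angle between the
#' emitter's gaze direction (head centre to snout) and the direction to the
#' receiver snout, folded into [0, 180] degrees (left/right hemispaces are
#' agglomerated: no lateral preference is assumed). A receiver directly
#' ahead is at 0 degrees.
#'
#' @param emitter_snout,emitter_head Length-2 positions (mm).
#' @param receiver_snout Length-2 position (mm).
#' @return Named vector `c(r, alpha)`: mm and degrees.
#' @export
relative_polar <- function(emitter_snout, emitter_head, receiver_snout) {
  gaze <- emitter_snout - emitter_head
  if (sum(gaze^2) == 0) stop("emitter snout and head centre coincide")
  v <- receiver_snout - emitter_snout
  r <- sqrt(sum(v^2))
  if (r == 0) return(c(r = 0, alpha = 0))
  ca <- sum(gaze * v) / (sqrt(sum(gaze^2)) * r)
  c(r = r, alpha = acos(pmin(pmax(ca, -1), 1)) * 180 / pi)
}

#' Polar raw-count occurrence histogram
#'
#' Bins relative polar positions with 10 degree x 1 cm bins (half-open
#' `[lo, hi)`); radii beyond `r_max` land in one overflow bin per angular
#' bin, so total mass equals the number of input points.
#'
#' @param r Radii (mm).
#' @param alpha Angles (degrees, in [0, 180]).
#' @param r_max Largest regular radial edge (mm).
#' @param dr,da Radial (mm) / angular (degree) bin widths.
#' @return A `polar_histogram`: list with `counts`
#'   (angle-bins x (radius-bins + overflow)), `angle_edges`,
#'   `radius_edges`, `n`.
#' @export
polar_histogram <- function(r, alpha, r_max = 200, dr = 10, da = 10) {
  stopifnot(all(r >= 0), all(alpha >= 0 - 1e-9), all(alpha <= 180 + 1e-9))
  a_edges <- seq(0, 180, by = da)
  r_edges <- seq(0, r_max, by = dr)
  na <- length(a_edges) - 1L
  nr <- length(r_edges) - 1L
  counts <- matrix(0L, na, nr + 1L)   # last column = radial overflow
  if (length(r)) {
    ai <- pmin(pmax(floor(alpha / da) + 1L, 1L), na)  # alpha == 180 -> last
    ri <- floor(r / dr) + 1L
    ri[ri > nr] <- nr + 1L
    for (i in seq_along(r)) counts[ai[i], ri[i]] <- counts[ai[i], ri[i]] + 1L
  }
  structure(list(counts = counts, angle_edges = a_edges,
                 radius_edges = r_edges, n = length(r)),
            class = "polar_histogram")
}

#' Marginal density of a polar histogram
#'
#' Sums over the other axis and normalizes to unit mass (per bin width).
#' Given several per-recording histograms, the mean density and its SEM
#' across recordings are returned.
#'
#' @param h A `polar_histogram` or a list of them (per recording).
#' @param axis `"radius"` or `"angle"`.
#' @param drop_overflow Exclude the radial overflow bin.
#' @return Data frame: bin_lo, bin_hi, density, sem.
#' @export
marginal_density <- function(h, axis = c("radius", "angle"),
                             drop_overflow = TRUE) {
  axis <- match.arg(axis)
  hs <- if (inherits(h, "polar_histogram")) list(h) else h
  one <- function(hh) {
    cnt <- hh$counts
    if (drop_overflow) cnt <- cnt[, -ncol(cnt), drop = FALSE]
    m <- if (axis == "radius") colSums(cnt) else rowSums(cnt)
    edges <- if (axis == "radius") hh$radius_edges else hh$angle_edges
    w <- diff(edges)
    dens <- if (sum(m) > 0) m / sum(m) / w else m * 0
    list(dens = dens, edges = edges)
  }
  res <- lapply(hs, one)
  dm <- vapply(res, `[[`, numeric(length(res[[1]]$dens)), "dens")
  dm <- matrix(dm, ncol = length(res))
  edges <- res[[1]]$edges
  data.frame(bin_lo = edges[-length(edges)], bin_hi = edges[-1],
             density = rowMeans(dm),
             sem = if (ncol(dm) > 1) apply(dm, 1, sd) / sqrt(ncol(dm))
                   else rep(NA_real_, nrow(dm)))
}

#' Bootstrap significance of a difference between two polar maps
#'
#' Tests, per bin, whether two sets of relative positions differ: both
#' groups are resampled with replacement `n_boot` times (default 100), each
#' bootstrap histogram density-normalized to sum 1, and the per-bin
#' difference distribution summarized by its extreme values; a bin is
#' flagged when the bootstrap difference interval (quantiles `level/2`,
#' `1 - level/2`; at 100 draws and level 0.01 these are the most extreme
#' values) excludes zero.
#'
#' @param points_a,points_b Data frames / matrices with columns `r`,
#'   `alpha` (mm, degrees).
#' @param n_boot Bootstrap repetitions (>= 2).
#' @param level Significance level.
#' @param r_max,dr,da Binning, see [polar_histogram()].
#' @return List: `significant` (logical bin matrix), `diff` (observed
#'   density difference A - B), `lower`, `upper` bound matrices.
#' @export
bootstrap_diff_significance <- function(points_a, points_b, n_boot = 100,
                                        level = 0.01, r_max = 200,
                                        dr = 10, da = 10) {
  if (n_boot < 2) stop("'n_boot' must be >= 2")
  pa <- as.data.frame(points_a); pb <- as.data.frame(points_b)
  if (!nrow(pa) || !nrow(pb)) stop("both point sets must be non-empty")
  dens <- function(p) {
    h <- polar_histogram(p$r, p$alpha, r_max, dr, da)
    h$counts / sum(h$counts)
  }
  obs <- dens(pa) - dens(pb)
  boots <- array(NA_real_, c(dim(obs), n_boot))
  for (b in seq_len(n_boot)) {
    ra <- pa[sample.int(nrow(pa), replace = TRUE), ]
    rb <- pb[sample.int(nrow(pb), replace = TRUE), ]
    boots[, , b] <- dens(ra) - dens(rb)
  }
  # type-1 (inverse-ECDF) quantiles: at level 0.01 with 100 draws these are
  # the most extreme bootstrap values, with no interpolation across zero
  lower <- apply(boots, c(1, 2), quantile, probs = level / 2, type = 1)
  upper <- apply(boots, c(1, 2), quantile, probs = 1 - level / 2, type = 1)
  list(significant = lower > 0 | upper < 0, diff = obs,
       lower = lower, upper = upper)
}

#' Fraction of assigned USVs attributed to female mice
#'
#' Computes the female fraction per recording and pooled, optionally
#' restricted to high-confidence assignments (MPI selection is already
#' implicit in `reason == "assigned"`) and/or to USVs emitted while all
#' snouts were more than `distance_gate` apart (read from the tracks at
#' each USV midpoint).
#'
#' @param assignments Assignment table(s): one data frame or a list (per
#'   recording) as produced by [assign_dataset()].
#' @param tracks Matching pose tracks (single or list).
#' @param distance_gate `NA` for no gating, or a minimum pairwise
#'   snout-snout distance in mm (e.g. 50).
#' @return List: `per_recording` fractions, `pooled` fraction (NA when no
#'   USV survives selection).
#' @export
female_fraction <- function(assignments, tracks, distance_gate = NA) {
  al <- if (is.data.frame(assignments)) list(assignments) else assignments
  tl <- if (is.data.frame(tracks)) list(tracks) else tracks
  nf <- 0L; nt <- 0L; per <- numeric(length(al))
  for (j in seq_along(al)) {
    a <- al[[j]][al[[j]]$reason == "assigned", , drop = FALSE]
    if (!is.na(distance_gate) && nrow(a)) {
      keep <- vapply(seq_len(nrow(a)), function(i) {
        pose <- pose_at(tl[[j]], (a$onset_s[i] + a$offset_s[i]) / 2)
        if (nrow(pose) < 2) return(TRUE)
        min(stats::dist(pose[, c("snout_x_mm", "snout_y_mm")])) >
          distance_gate
      }, logical(1))
      a <- a[keep, , drop = FALSE]
    }
    sex <- tl[[j]]$sex[match(a$mouse_id, tl[[j]]$mouse_id)]
    per[j] <- if (nrow(a)) mean(sex == "F") else NA_real_
    nf <- nf + sum(sex == "F"); nt <- nt + nrow(a)
  }
  list(per_recording = per, pooled = if (nt) nf / nt else NA_real_)
}

#' Plot a relative polar occurrence histogram
#'
#' Tile plot of the binned relative positions of receiver mice around
#' emitters (angle 0 = straight ahead of the emitter's gaze). Requires
#' ggplot2.
#'
#' @param h A `polar_histogram`.
#' @param drop_overflow Exclude the radial overflow bin.
#' @return A ggplot object.
#' @export
plot_polar_histogram <- function(h, drop_overflow = TRUE) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plot_polar_histogram() needs the 'ggplot2' package")
  cnt <- h$counts
  if (drop_overflow) cnt <- cnt[, -ncol(cnt), drop = FALSE]
  df <- expand.grid(
    alpha = (h$angle_edges[-length(h$angle_edges)] +
             h$angle_edges[-1]) / 2,
    r = (h$radius_edges[-length(h$radius_edges)] +
         h$radius_edges[-1]) / 2)
  df$count <- as.vector(cnt)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$alpha, y = .data$r,
                                   fill = .data$count)) +
    ggplot2::geom_tile() +
    ggplot2::coord_polar(theta = "x", start = -pi / 2, direction = -1) +
    ggplot2::scale_x_continuous(limits = c(0, 360),
                                breaks = seq(0, 180, 45)) +
    ggplot2::labs(x = "angle from emitter gaze (deg)",
                  y = "snout-snout distance (mm)", fill = "USVs") +
    ggplot2::theme_minimal()
}

#' Dominance classification within a same-sex pair
#'
#' In a triadic recording the two same-sex mice are split into dominant
#' and subordinate by who vocalized more; a tie leaves both unlabeled.
#'
#' @param counts Named vector of per-mouse USV counts.
#' @param sexes Named vector of sexes for the same mice.
#' @return Named character vector ("dominant"/"subordinate") for the
#'   same-sex pair, or `NULL` when no same-sex pair exists or on a tie.
#' @export
classify_dominance <- function(counts, sexes) {
  if (any(is.na(counts))) stop("missing counts")
  sexes <- sexes[names(counts)]
  tab <- table(sexes)
  pair_sex <- names(tab)[tab == 2]
  if (length(pair_sex) != 1) return(NULL)
  pair <- names(counts)[sexes == pair_sex]
  cp <- counts[pair]
  if (cp[1] == cp[2]) return(NULL)
  out <- c("dominant", "subordinate")[order(-cp)]
  names(out) <- pair[order(-cp)]
  out[pair]
}

#' Nonparametric group comparisons for recording summaries
#'
#' Thin wrappers over the standard nonparametric tests used for
#' group-level behavioral comparisons: Wilcoxon rank-sum for two groups,
#' Kruskal-Wallis for more, Spearman correlation for paired continuous
#' measures, with optional Bonferroni correction across a panel of tests.
#'
#' @param values Numeric response.
#' @param groups Grouping factor (for `usv_group_test`) or second numeric
#'   vector (for `usv_correlation`).
#' @param n_tests Number of tests in the panel (Bonferroni multiplier).
#' @return List with `statistic`, `p_value`, `p_adjusted`, `method`.
#' @export
usv_group_test <- function(values, groups, n_tests = 1) {
  groups <- factor(groups)
  if (nlevels(groups) == 2) {
    ht <- stats::wilcox.test(values ~ groups, exact = FALSE)
  } else {
    ht <- stats::kruskal.test(values, groups)
  }
  list(statistic = unname(ht$statistic), p_value = ht$p.value,
       p_adjusted = min(1, ht$p.value * n_tests), method = ht$method)
}

#' @rdname usv_group_test
#' @export
usv_correlation <- function(values, groups, n_tests = 1) {
  ht <- suppressWarnings(
    stats::cor.test(values, groups, method = "spearman"))
  list(statistic = unname(ht$estimate), p_value = ht$p.value,
       p_adjusted = min(1, ht$p.value * n_tests), method = ht$method)
}
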
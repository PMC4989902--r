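# Circumferential averaging of strain as a function of distance to the
# airway, and its assembly over time into kymographs.

#' Euclidean distance map to the airway lumen
#'
#' For every pixel outside the lumen, the straight-line distance to the
#' nearest lumen pixel, in micrometres; exactly 0 on and inside the
#' lumen.
#'
#' @param lumen_mask logical matrix, `TRUE` on the lumen.
#' @param pixel_size um/px.
#' @return numeric matrix of distances (um).
#' @export
distance_map <- function(lumen_mask, pixel_size) {
  if (!any(lumen_mask)) stopf("distance map of an empty lumen mask")
  d <- EBImage::distmap(1 - lumen_mask, metric = "euclidean")
  as.matrix(d) * pixel_size
}

#' Distance-binned circumferential strain averages
#'
#' Sorts (distance-to-airway, strain) couples into half-open distance bins
#' `[k w, (k+1) w)` and averages the major and minor principal strains in
#' each bin.  Grid points off tissue (whose strains were zeroed) are
#' excluded from the averages — including them would bias bin means toward
#' zero.  Empty bins are reported as missing (`NA`), not zero.
#'
#' @param strain_field a [strain_field()].
#' @param dmap distance map (um) from [distance_map()], frame-sized.
#' @param bin_width bin width in um (default 15).
#' @return data.frame of class `radial_profile`: `bin_center_um`,
#'   `mean_major`, `mean_minor`, `n`.
#' @export
bin_average <- function(strain_field, dmap, bin_width = 15) {
  sfd <- as.data.frame(strain_field)
  d_um <- dmap[cbind(sfd$Y_px + 1, sfd$X_px + 1)]
  keep <- sfd$on_tissue
  d_keep <- d_um[keep]
  if (length(d_keep) == 0L) {
    warnf("no tissue grid points to bin")
    out <- data.frame(bin_center_um = numeric(0), mean_major = numeric(0),
                      mean_minor = numeric(0), n = integer(0))
    class(out) <- c("radial_profile", "data.frame")
    attr(out, "bin_width") <- bin_width
    return(out)
  }
  nbin <- floor(max(d_keep) / bin_width) + 1L
  bin <- pmin(floor(d_keep / bin_width), nbin - 1L) + 1L   # 1-based bin id
  n <- tabulate(bin, nbins = nbin)
  sum_maj <- rep(0, nbin); sum_min <- rep(0, nbin)
  maj <- sfd$lambda_major[keep]; mino <- sfd$lambda_minor[keep]
  for (b in unique(bin)) {
    sel <- bin == b
    sum_maj[b] <- sum(maj[sel]); sum_min[b] <- sum(mino[sel])
  }
  out <- data.frame(
    bin_center_um = (seq_len(nbin) - 0.5) * bin_width,
    mean_major = ifelse(n > 0, sum_maj / n, NA_real_),
    mean_minor = ifelse(n > 0, sum_min / n, NA_real_),
    n = n)
  class(out) <- c("radial_profile", "data.frame")
  attr(out, "bin_width") <- bin_width
  out
}

#' Stack radial profiles over time into a kymograph
#'
#' Columns are time points, rows are distance bins; missing bins propagate
#' as `NA`.  Profiles shorter than the longest one are padded with missing
#' bins; inconsistent bin widths are an error.
#'
#' @param profiles list of [bin_average()] results, one per frame.
#' @param times acquisition times (s), one per profile.
#' @return object of class `kymograph`: matrices `major` and `minor`
#'   (bins x times), `counts`, `bin_centers_um`, `times_s`, `bin_width`.
#' @export
kymograph <- function(profiles, times) {
  if (length(profiles) == 0L) stopf("no profiles to stack")
  if (length(times) != length(profiles))
    stopf("times length (%d) != number of profiles (%d)",
          length(times), length(profiles))
  bws <- vapply(profiles, function(p) attr(p, "bin_width"), numeric(1))
  if (length(unique(bws)) != 1L)
    stopf("profiles have inconsistent bin widths: %s",
          paste(unique(bws), collapse = ", "))
  bw <- bws[1]
  for (p in profiles) {
    k <- nrow(p)
    if (k > 0 && any(abs(p$bin_center_um - ((seq_len(k) - 0.5) * bw)) >
                     1e-9))
      stopf("profiles have inconsistent bin edges")
  }
  nbin <- max(vapply(profiles, nrow, integer(1)))
  nt <- length(profiles)
  maj <- matrix(NA_real_, nbin, nt)
  mino <- matrix(NA_real_, nbin, nt)
  cnt <- matrix(0L, nbin, nt)
  for (j in seq_len(nt)) {
    k <- nrow(profiles[[j]])
    if (k > 0) {
      maj[seq_len(k), j] <- profiles[[j]]$mean_major
      mino[seq_len(k), j] <- profiles[[j]]$mean_minor
      cnt[seq_len(k), j] <- profiles[[j]]$n
    }
  }
  structure(list(major = maj, minor = mino, counts = cnt,
                 bin_centers_um = (seq_len(nbin) - 0.5) * bw,
                 times_s = as.numeric(times), bin_width = bw),
            class = "kymograph")
}

#' @export
print.kymograph <- function(x, ...) {
  cat(sprintf("<kymograph> %d distance bins (%g um) x %d time points (%g..%g s)\n",
              length(x$bin_centers_um), x$bin_width, length(x$times_s),
              min(x$times_s), max(x$times_s)))
  invisible(x)
}

#' Strain time series at fixed distances from the airway
#'
#' Extracts the kymograph rows whose bins contain the requested distances
#' (containment rule: distance d falls in bin `[k w, (k+1) w)`).
#'
#' @param kymo a [kymograph()].
#' @param distances_um distances from the airway lumen (um); default
#'   `c(0, 15, 30, 45, 60)`.
#' @param component `"major"` (radial) or `"minor"` (circumferential).
#' @return data.frame: `distance_um` (as requested), `bin_center_um`,
#'   `time_s`, `strain`.
#' @export
strain_time_series <- function(kymo, distances_um = c(0, 15, 30, 45, 60),
                               component = c("major", "minor")) {
  component <- match.arg(component)
  bw <- kymo$bin_width
  nbin <- length(kymo$bin_centers_um)
  bin_idx <- floor(distances_um / bw) + 1L
  bad <- distances_um < 0 | bin_idx > nbin
  if (any(bad))
    stopf("distance(s) %s um outside the mapped range [0, %g) um",
          paste(distances_um[bad], collapse = ", "), nbin * bw)
  mat <- kymo[[component]]
  do.call(rbind, lapply(seq_along(distances_um), function(i) {
    data.frame(distance_um = distances_um[i],
               bin_center_um = kymo$bin_centers_um[bin_idx[i]],
               time_s = kymo$times_s,
               strain = mat[bin_idx[i], ])
  }))
}
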
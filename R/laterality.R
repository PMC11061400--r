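# Channel-to-region mapping, lesion-orientation normalization and the
# laterality index LI = (mean beta contralateral - mean beta ipsilateral) /
# (mean beta contralateral + mean beta ipsilateral), per cortical region of
# interest (PMC, M1, S1).

#' Default 24-channel region map
#'
#' The montage symmetrically covers premotor cortex (PMC), primary motor
#' cortex (M1) and somatosensory cortex (S1) on both hemispheres: 3 regions x
#' 2 hemispheres x 4 channels.  Channels 1-12 are left-hemisphere, 13-24
#' right; channel k mirrors channel k +/- 12.  The exact probe coordinates of
#' any given montage differ, so the map is user-replaceable
#' (\code{\link{read_region_map}}); this default is a documented stand-in
#' with the correct symmetry.
#'
#' @return data.frame with columns \code{channel}, \code{region},
#'   \code{hemisphere}, \code{mirror}.
#' @export
default_region_map <- function() {
  region <- rep(rep(c("PMC", "M1", "S1"), each = 4L), times = 2L)
  hemisphere <- rep(c("left", "right"), each = 12L)
  channel <- seq_len(24L)
  mirror <- c(13:24, 1:12)
  data.frame(channel = channel, region = region, hemisphere = hemisphere,
             mirror = mirror, stringsAsFactors = FALSE)
}

#' Read a region map from YAML
#'
#' Expected layout: one entry per channel,
#' \code{ch01: {region: PMC, hemisphere: left, mirror: 13}}.
#'
#' @param path YAML file path.
#' @return region-map data.frame as in \code{\link{default_region_map}}.
#' @export
read_region_map <- function(path) {
  y <- yaml::read_yaml(path)
  ch <- as.integer(sub("^ch", "", names(y)))
  out <- data.frame(channel = ch,
                    region = vapply(y, function(e) e$region, character(1)),
                    hemisphere = vapply(y, function(e) e$hemisphere, character(1)),
                    mirror = vapply(y, function(e) as.integer(e$mirror), integer(1)),
                    stringsAsFactors = FALSE)
  out[order(out$channel), , drop = FALSE]
}

# internal: check the map covers every channel with non-empty region cells
validate_region_map <- function(map, n_channels = 24L) {
  if (!setequal(map$channel, seq_len(n_channels)))
    stop_strokesyn("region map must cover every channel exactly once",
                   "strokesyn_regionmap_error")
  if (!all(map$mirror[match(map$mirror, map$channel)] == map$channel))
    stop_strokesyn("region map mirrors are not an involution",
                   "strokesyn_regionmap_error")
  cells <- table(map$region, map$hemisphere)
  if (any(cells == 0))
    stop_strokesyn("every region x hemisphere cell must contain channels",
                   "strokesyn_regionmap_error")
  invisible(map)
}

#' Normalize lesion orientation of a beta map
#'
#' By convention the right hemisphere is treated as the affected hemisphere:
#' for patients whose lesion is in the left hemisphere, each channel's beta
#' is swapped with its mirror channel; right-lesion patients and controls
#' pass through unchanged.  Applying the swap twice is the identity.
#'
#' @param beta numeric vector of per-channel betas (or a \code{beta_map}).
#' @param lesion_side "left", "right" or "none".
#' @param map region map with a \code{mirror} column.
#' @return beta vector (or \code{beta_map}) in oriented space.
#' @export
normalize_lesion_orientation <- function(beta, lesion_side, map = default_region_map()) {
  lesion_side <- match.arg(lesion_side, c("left", "right", "none"))
  is_bm <- inherits(beta, "beta_map")
  b <- if (is_bm) beta$beta else beta
  validate_region_map(map, n_channels = length(b))
  if (lesion_side == "left") {
    b <- b[map$mirror[order(map$channel)]]
  }
  if (is_bm) { beta$beta <- b; beta } else b
}

#' Laterality index per region of interest
#'
#' \code{LI = (bC - bI) / (bC + bI)} where \code{bC}/\code{bI} are the mean
#' betas over the channels of the region on the hemisphere contralateral/
#' ipsilateral to the moving arm.  In oriented space (right hemisphere =
#' affected) movement of the affected arm has the right hemisphere
#' contralateral, movement of the unaffected arm the left.  When
#' \code{|bC + bI|} falls below \code{tol} the LI is reported missing.
#'
#' @param beta oriented per-channel beta vector (or \code{beta_map}).
#' @param map region map.
#' @param moving_arm "affected" or "unaffected".
#' @param tol denominator tolerance.
#' @return list of class \code{"laterality_result"} with \code{li} (named
#'   vector over regions), \code{beta_contra}, \code{beta_ipsi},
#'   \code{moving_arm}, \code{flagged} (regions with mixed-sign betas whose
#'   LI may leave [-1, 1]).
#' @export
laterality_index <- function(beta, map = default_region_map(),
                             moving_arm = c("affected", "unaffected"),
                             tol = 1e-12) {
  moving_arm <- match.arg(moving_arm)
  if (inherits(beta, "beta_map")) beta <- beta$beta
  validate_region_map(map, n_channels = length(beta))
  contra_hemi <- if (moving_arm == "affected") "right" else "left"
  regions <- sort(unique(map$region))
  li <- setNames(rep(NA_real_, length(regions)), regions)
  bC <- li; bI <- li
  flagged <- character(0)
  for (r in regions) {
    cC <- map$channel[map$region == r & map$hemisphere == contra_hemi]
    cI <- map$channel[map$region == r & map$hemisphere != contra_hemi]
    bC[r] <- mean(beta[cC]); bI[r] <- mean(beta[cI])
    if (abs(bC[r] + bI[r]) >= tol) li[r] <- (bC[r] - bI[r]) / (bC[r] + bI[r])
    if (bC[r] * bI[r] < 0) flagged <- c(flagged, r)
  }
  structure(list(li = li, beta_contra = bC, beta_ipsi = bI,
                 moving_arm = moving_arm, flagged = flagged),
            class = "laterality_result")
}

#' @export
print.laterality_result <- function(x, ...) {
  cat(sprintf("laterality indices (%s arm moving):\n", x$moving_arm))
  for (r in names(x$li))
    cat(sprintf("  %-4s LI = %s%s\n", r,
                if (is.na(x$li[r])) "missing" else sprintf("%+.4f", x$li[r]),
                if (r %in% x$flagged) "  [mixed-sign betas]" else ""))
  invisible(x)
}
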
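#' The 26 cognitive electrodes of the 256-channel geodesic net
#'
#' Channel labels designated in the vendor documentation of the 256-channel
#' geodesic sensor net as optimal for observing cognitive ERPs; they cover the
#' centro-parietal and centro-occipital scalp.
#'
#' @format Character vector of length 26.
#' @export
cognitive_channels <- c(
  "E98", "E99", "E100", "E101", "E108", "E109", "E110", "E116", "E117",
  "E118", "E119", "E124", "E125", "E126", "E127", "E128", "E129", "E137",
  "E138", "E139", "E140", "E141", "E149", "E150", "E151", "E152"
)

#' Build the idealized 256-channel scalp montage
#'
#' Constructs a deterministic montage of 256 electrode positions on the unit
#' sphere using a Fibonacci spiral layout. Exact manufacturer coordinates are
#' not used; only the relative geometry matters downstream (spatial
#' neighbourhoods for interpolation, and the posterior/frontal split used by
#' the synthetic-signal generator). The 26 cognitive channels are mapped onto
#' the contiguous posterior cap, and the highest-numbered remaining labels are
#' mapped onto the anterior-inferior (face) region, mirroring the real net
#' where high-numbered sensors sit near the eyes and cheeks.
#'
#' Coordinates: x right, y anterior, z superior; all positions have unit norm.
#'
#' @return An object of class `eeg_montage`: a list with `labels` (character,
#'   length 256), `positions` (256 x 3 matrix, rownames = labels) and
#'   `cognitive_subset` (character, length 26).
#' @examples
#' m <- build_montage()
#' range(sqrt(rowSums(m$positions^2)))
#' @export
build_montage <- function() {
  n <- 256L
  # Fibonacci sphere, slightly flattened below to emulate a cap that does not
  # extend to the neck: keep z in [-0.6, 1] by restricting the spiral.
  i <- seq_len(n) - 0.5
  z <- 1 - i / n * 1.6 # from ~1 down to -0.6
  r <- sqrt(pmax(0, 1 - z^2))
  golden <- pi * (3 - sqrt(5))
  theta <- golden * (seq_len(n) - 1)
  pos <- cbind(x = r * cos(theta), y = r * sin(theta), z = z)
  pos <- pos / sqrt(rowSums(pos^2))

  labels <- paste0("E", seq_len(n))
  cog <- cognitive_channels

  # Cognitive subset: the 26 sensors closest (by angle) to the
  # centro-parieto-occipital direction.
  post_dir <- c(0, -0.80, -0.35)
  post_dir <- post_dir / sqrt(sum(post_dir^2))
  ang <- acos(pmin(1, pmax(-1, pos %*% post_dir)))
  cog_idx <- order(ang)[seq_along(cog)]
  # order cognitive points by azimuth for a stable, readable assignment
  cog_idx <- cog_idx[order(atan2(pos[cog_idx, "y"], pos[cog_idx, "x"]),
                           pos[cog_idx, "z"])]

  rest_idx <- setdiff(seq_len(n), cog_idx)
  # Face score: anterior and inferior sensors score high; highest-numbered
  # free labels go to the face region.
  face_score <- pos[rest_idx, "y"] - pos[rest_idx, "z"]
  rest_idx <- rest_idx[order(face_score)]
  rest_labels <- setdiff(labels, cog)

  perm <- integer(n)
  perm[cog_idx] <- match(cog, labels)
  perm[rest_idx] <- match(rest_labels, labels)

  ordered_pos <- matrix(NA_real_, n, 3, dimnames = list(labels, c("x", "y", "z")))
  ordered_pos[perm, ] <- pos
  out <- structure(
    list(labels = labels, positions = ordered_pos, cognitive_subset = cog),
    class = "eeg_montage"
  )
  out
}

#' @export
print.eeg_montage <- function(x, ...) {
  cat("<eeg_montage> ", length(x$labels), " channels, ",
      length(x$cognitive_subset), " cognitive channels\n", sep = "")
  invisible(x)
}

# Scalar angular distances between channel positions (radians).
montage_distances <- function(montage, labels = montage$labels) {
  p <- montage$positions[labels, , drop = FALSE]
  g <- pmin(pmax(tcrossprod(p), -1), 1)
  acos(g)
}

# Smooth scalp topography: Gaussian-in-angle weight around a unit direction.
# `width` is the angular scale in radians. `floor` adds a far-field tail
# (volume conduction reaches every sensor, so no scalp site is ever fully
# decoupled from a source).
scalp_topography <- function(montage, center, width = 0.5, floor = 0,
                             labels = montage$labels) {
  center <- center / sqrt(sum(center^2))
  cosang <- pmin(pmax(montage$positions[labels, , drop = FALSE] %*% center, -1), 1)
  w <- exp((cosang - 1) / width^2) + floor
  as.numeric(w)
}
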
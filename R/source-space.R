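# Toy source space: a small set of cortical "areas" on a shell inside
# the conducting sphere, with a few point sources per area.  Stands in
# for an anatomical atlas grid; any real atlas can be used through the
# generic point -> label interface of `label_sources()`.

#' Toy cortical atlas on a spherical shell
#'
#' Twelve areas (six anterior, six posterior, left/right symmetric) with
#' centroids on a shell of 7 cm radius. Area names use conventional
#' abbreviations (l/r prefix for hemisphere); the anterior set covers
#' frontal-medial, paracingulate and inferior-temporal territory, the
#' posterior set occipital-lateral, supramarginal and precuneus
#' territory, so that anterior/posterior group effects can be stated on
#' familiar labels.
#'
#' @param shell_radius centroid shell radius in m.
#' @param area_radius assignment radius of each area in m (sources
#'   farther than this from every centroid stay unlabeled).
#' @return data.frame with `area`, `x`, `y`, `z`, `radius`, `region`
#'   (anterior/posterior).
#' @export
toy_atlas <- function(shell_radius = 0.07, area_radius = 0.02) {
  # longitude lambda measured from +y (front); posterior areas at y < 0
  def <- data.frame(
    area = c("lFMC", "rFMC", "lParaC", "rParaC", "lITG", "rITG",
             "lSOC", "rSOC", "lSMG", "rSMG", "lPCu", "rPCu"),
    lat = c(30, 30, 55, 55, 15, 15,
            20, 20, 40, 40, 52, 52),
    lon = c(-30, 30, -18, 18, -70, 70,
            -150, 150, -108, 108, -158, 158),
    region = rep(c("anterior", "posterior"), each = 6),
    stringsAsFactors = FALSE
  )
  lat <- def$lat * pi / 180
  lon <- def$lon * pi / 180
  def$x <- shell_radius * cos(lat) * sin(lon)
  def$y <- shell_radius * cos(lat) * cos(lon)
  def$z <- shell_radius * sin(lat)
  def$radius <- area_radius
  def[, c("area", "x", "y", "z", "radius", "region")]
}

#' Place point sources around atlas centroids
#'
#' @param atlas a data.frame as returned by [toy_atlas].
#' @param sources_per_area number of sources per area.
#' @param jitter_sd spatial scatter around each centroid (m).
#' @param seed integer seed.
#' @return list with `positions` (n x 3), `orientations` (n x 3,
#'   tangential unit vectors), `labels` (area per source).
#' @export
place_area_sources <- function(atlas, sources_per_area = 2L,
                               jitter_sd = 0.005, seed = NULL) {
  local_seed(seed, {
    n <- nrow(atlas) * sources_per_area
    pos <- matrix(0, n, 3)
    labels <- character(n)
    k <- 0L
    for (i in seq_len(nrow(atlas))) {
      cen <- as.numeric(atlas[i, c("x", "y", "z")])
      for (s in seq_len(sources_per_area)) {
        k <- k + 1L
        p <- cen + stats::rnorm(3, sd = jitter_sd)
        # keep sources strictly inside the shell the sensors sit on
        if (sqrt(sum(p^2)) > 0.085) p <- p * 0.085 / sqrt(sum(p^2))
        pos[k, ] <- p
        labels[k] <- atlas$area[i]
      }
    }
    # tangential orientations: random direction orthogonal to the radius
    ori <- matrix(0, n, 3)
    for (k in seq_len(n)) {
      r <- pos[k, ] / sqrt(sum(pos[k, ]^2))
      v <- stats::rnorm(3)
      v <- v - sum(v * r) * r
      ori[k, ] <- v / sqrt(sum(v^2))
    }
    list(positions = pos, orientations = ori, labels = labels)
  })
}

#' Label sources by atlas area
#'
#' Assigns each source position to the nearest atlas area centroid; a
#' source farther than the area's assignment radius from every centroid
#' is left unlabeled and masked out (such sources are discarded from all
#' downstream analysis, mirroring the removal of grid points that fall
#' outside recognized areas).
#'
#' @param positions matrix `n x 3` of source positions (m).
#' @param atlas a data.frame with columns `area`, `x`, `y`, `z`,
#'   `radius`.
#' @return a `source_space` object: list with `positions`,
#'   `atlas_label` (NA for unlabeled), `retained_mask`, `area_names`.
#' @export
label_sources <- function(positions, atlas) {
  positions <- as.matrix(positions)
  if (nrow(atlas) == 0L) stop("atlas is empty", call. = FALSE)
  cen <- as.matrix(atlas[, c("x", "y", "z")])
  lab <- rep(NA_character_, nrow(positions))
  for (i in seq_len(nrow(positions))) {
    d <- sqrt(colSums((t(cen) - positions[i, ])^2))
    j <- which.min(d)
    if (d[j] <= atlas$radius[j]) lab[i] <- atlas$area[j]
  }
  structure(
    list(
      positions = positions,
      atlas_label = lab,
      retained_mask = !is.na(lab),
      area_names = atlas$area
    ),
    class = "source_space"
  )
}

#' @export
print.source_space <- function(x, ...) {
  cat(sprintf("<source_space> %d source(s), %d retained, %d area(s)\n",
              nrow(x$positions), sum(x$retained_mask),
              length(unique(stats::na.omit(x$atlas_label)))))
  invisible(x)
}

#' Default resting-state-network definitions for the toy atlas
#'
#' Membership lists for the dorsal attention network (DAN) and the
#' anterior and posterior components of the default mode network
#' (aDMN/pDMN), expressed as toy-atlas areas. Real analyses supply their
#' own membership lists; the anterior and posterior DMN components are
#' disjoint by construction.
#'
#' @return named list of character vectors.
#' @export
default_rsn_definitions <- function() {
  list(
    DAN = c("lSMG", "rSMG", "lPCu", "rPCu"),
    aDMN = c("lFMC", "rFMC", "lParaC", "rParaC"),
    pDMN = c("lPCu", "rPCu", "lSOC", "rSOC")
  )
}
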
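# 30-channel 10/10 recording montage used throughout the package.

# BESA-style spherical coordinates (theta: inclination from the vertex,
# negative = left hemisphere; phi: azimuth, positive rotates towards the
# back for left-hemisphere sites). Radius is taken as 1 (unit sphere).
.montage_besa <- data.frame(
  name  = c("Fp1", "Fp2", "F7",  "F3",  "Fz",  "F4",  "F8",
            "FC5", "FC1", "FC2", "FC6", "T7",  "C3",  "Cz",
            "C4",  "T8",  "TP9", "CP5", "CP1", "CP2", "CP6",
            "TP10","P7",  "P3",  "Pz",  "P4",  "P8",  "O1",
            "Oz",  "O2"),
  theta = c(-92,  92, -92, -60,  46,  60,  92,
            -72, -32,  32,  72, -92, -46,   0,
             46,  92, -108, -72, -32,  32,  72,
            108, -92, -60,  46,  60,  92, -92,
             92,  92),
  phi   = c(-72,  72, -36, -51,  90,  51,  36,
            -21, -45,  45,  21,   0,   0,   0,
              0,   0,  18,  21,  45, -45, -21,
            -18,  36,  51, -90, -51, -36,  72,
            -90, -72),
  stringsAsFactors = FALSE
)

#' Standard 30-channel recording montage
#'
#' Channel names and unit-sphere scalp positions of the 30-channel 10/10
#' cap used for the disorders-of-consciousness recordings (Fp1 ... O2).
#' The row order of this table is the canonical channel order: every
#' matrix and per-electrode vector in the package uses it.
#'
#' @return A data frame with columns `name`, `x`, `y`, `z` (Cartesian
#'   position on the unit sphere; `+x` right, `+y` anterior, `+z` vertex)
#'   and 30 rows.
#' @export
#' @examples
#' m <- doc_montage()
#' nrow(m)            # 30
#' m$name[m$z > 0.9]  # vertex electrode
doc_montage <- function() {
  th <- .montage_besa$theta * pi / 180
  ph <- .montage_besa$phi * pi / 180
  data.frame(
    name = .montage_besa$name,
    x = sin(th) * cos(ph),
    y = sin(th) * sin(ph),
    z = cos(th),
    stringsAsFactors = FALSE
  )
}

#' Centro-parietal electrode set
#'
#' The eight centro-parietal electrodes whose betweenness-centrality
#' variability tracks the consciousness score; used as the planted hub
#' set by the synthetic-cohort generator and as the recovery target in
#' per-electrode contrasts.
#'
#' @return Character vector of eight channel names.
#' @export
centro_parietal_electrodes <- function() {
  c("Cz", "C3", "C4", "CP1", "CP2", "Pz", "P3", "P4")
}

# Great-circle (angular) distance matrix between montage positions.
montage_distances <- function(montage = doc_montage()) {
  p <- as.matrix(montage[, c("x", "y", "z")])
  cosang <- tcrossprod(p)
  cosang <- pmin(pmax(cosang, -1), 1)
  d <- acos(cosang)
  dimnames(d) <- list(montage$name, montage$name)
  d
}
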
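#' Synthetic channel layouts for the wet and dry cap
#'
#' Returns an idealized sensor layout on the unit sphere for the two simulated
#' systems:
#'
#' * `"wet64"`: 61 scalp electrodes with 10-10 style labels (FCz is the
#'   mismatch-negativity analysis channel), three periocular EOG electrodes
#'   (above, below and lateral to the left eye) and two mastoids (M1, M2).
#' * `"dry64"`: 62 scalp electrodes on a near-equidistant numeric grid with
#'   row/column labels (`3Z` is the analysis channel; `1L` and `1LD` are the
#'   frontal references used for the bipolar EOG derivation), two periocular
#'   EOG electrodes (below and lateral to the left eye) and two mastoids.
#'
#' Positions are idealized: scalp sites are placed by an inverse azimuthal
#' equidistant projection from the vertex (rows/columns on an 18 degree grid),
#' which preserves the topology a spherical-spline interpolator needs but does
#' not reproduce any manufacturer's cap geometry.
#'
#' @param name `"wet64"` or `"dry64"`.
#' @return data.frame with columns `label`, `x`, `y`, `z` (unit sphere;
#'   +y nose, +x right, +z vertex), `type` (`scalp`, `eog`, `mastoid`),
#'   and attributes `mmn_channel`, `frontocentral` (channels receiving the
#'   evoked response, with gains), `eog_map` (named list describing the
#'   bipolar EOG derivation) and `system`.
#' @export
channel_layout <- function(name = c("wet64", "dry64")) {
  name <- match.arg(name)
  if (name == "wet64") wet_layout() else dry_layout()
}

# place a site given front-back and left-right grid angles (degrees):
# inverse azimuthal equidistant projection from the vertex.
grid_position <- function(front_deg, right_deg) {
  incl <- sqrt(front_deg^2 + right_deg^2) * pi / 180
  az <- atan2(right_deg, front_deg)  # 0 = straight ahead
  c(x = sin(incl) * sin(az), y = sin(incl) * cos(az), z = cos(incl))
}

wet_layout <- function() {
  rows <- list(
    Fp = list(f = 4, cols = c(-1, 0, 1)),
    AF = list(f = 3, cols = c(-3.5, -1.5, 0, 1.5, 3.5)),
    F  = list(f = 2, cols = -4:4),
    FC = list(f = 1, cols = -4:4),
    C  = list(f = 0, cols = -4:4),
    CP = list(f = -1, cols = -4:4),
    P  = list(f = -2, cols = -4:4),
    PO = list(f = -3, cols = c(-3.5, -1.5, 0, 1.5, 3.5)),
    O  = list(f = -4, cols = c(-1, 0, 1))
  )
  lab_num <- function(prefix, c) {
    if (abs(c) < 1e-9) return(paste0(prefix, "z"))
    # odd numbers on the left, even on the right, increasing outward;
    # half-step columns (AF/PO rows) land on the 3/7 positions
    n <- round(if (abs(c) %% 1 > 0) 2 * abs(c) else 2 * abs(c) - 1)
    paste0(prefix, if (c < 0) n else n + 1)
  }
  special <- c("FC-4" = "FT7", "FC4" = "FT8", "C-4" = "T7", "C4" = "T8",
               "CP-4" = "TP7", "CP4" = "TP8")
  labels <- character(0); pos <- NULL; typ <- character(0)
  for (r in names(rows)) {
    f <- rows[[r]]$f
    for (c in rows[[r]]$cols) {
      key <- paste0(r, c)
      lab <- if (key %in% names(special)) special[[key]] else lab_num(r, c)
      labels <- c(labels, lab)
      pos <- rbind(pos, grid_position(f * 18, c * 18))
      typ <- c(typ, "scalp")
    }
  }
  stopifnot(length(labels) == 61)
  extra <- rbind(
    EOGa = c(sin(1.85) * sin(-0.35), sin(1.85) * cos(-0.35), cos(1.85)),
    EOGb = c(sin(2.05) * sin(-0.35), sin(2.05) * cos(-0.35), cos(2.05)),
    EOGl = c(sin(1.95) * sin(-0.60), sin(1.95) * cos(-0.60), cos(1.95)),
    M1   = c(sin(2.0) * sin(-1.7), sin(2.0) * cos(-1.7), cos(2.0)),
    M2   = c(sin(2.0) * sin(1.7), sin(2.0) * cos(1.7), cos(2.0))
  )
  labels <- c(labels, rownames(extra))
  pos <- rbind(pos, extra)
  typ <- c(typ, "eog", "eog", "eog", "mastoid", "mastoid")
  out <- data.frame(label = labels, x = pos[, 1], y = pos[, 2], z = pos[, 3],
                    type = typ, stringsAsFactors = FALSE)
  fc <- c(FCz = 1, Fz = 0.8, Cz = 0.7, FC1 = 0.7, FC2 = 0.7, F1 = 0.5, F2 = 0.5,
          C1 = 0.45, C2 = 0.45)
  structure(out,
            system = "wet",
            mmn_channel = "FCz",
            frontocentral = fc,
            eog_map = list(veog = c("EOGa", "EOGb"), heog = c("EOGl", "F7")),
            mastoids = c("M1", "M2"))
}

dry_layout <- function() {
  counts <- c(5, 7, 9, 9, 9, 9, 7, 5, 2)  # rows front to back, 62 sites
  fronts <- c(72, 54, 36, 18, 0, -18, -36, -54, -72)
  suffixes <- c("Z", "L", "R", "LD", "RD", "LE", "RE", "LF", "RF")
  labels <- character(0); pos <- NULL
  for (i in seq_along(counts)) {
    n <- counts[i]
    if (n %% 2 == 1) {
      cols <- c(0, as.vector(t(cbind(-seq_len((n - 1) / 2), seq_len((n - 1) / 2)))))
      labs <- paste0(i, suffixes[seq_len(n)])
    } else {
      cols <- c(-1, 1)  # occipital pair, no midline site
      labs <- paste0(i, c("L", "R"))
    }
    labels <- c(labels, labs)
    for (j in seq_along(cols)) pos <- rbind(pos, grid_position(fronts[i], cols[j] * 18))
  }
  stopifnot(length(labels) == 62)
  extra <- rbind(
    EOGb = c(sin(2.05) * sin(-0.35), sin(2.05) * cos(-0.35), cos(2.05)),
    EOGl = c(sin(1.95) * sin(-0.60), sin(1.95) * cos(-0.60), cos(1.95)),
    M1   = c(sin(2.0) * sin(-1.7), sin(2.0) * cos(-1.7), cos(2.0)),
    M2   = c(sin(2.0) * sin(1.7), sin(2.0) * cos(1.7), cos(2.0))
  )
  labels <- c(labels, rownames(extra))
  pos <- rbind(pos, extra)
  typ <- c(rep("scalp", 62), "eog", "eog", "mastoid", "mastoid")
  out <- data.frame(label = labels, x = pos[, 1], y = pos[, 2], z = pos[, 3],
                    type = typ, stringsAsFactors = FALSE)
  fc <- c(`3Z` = 1, `2Z` = 0.8, `4Z` = 0.7, `3L` = 0.7, `3R` = 0.7,
          `2L` = 0.5, `2R` = 0.5, `4L` = 0.45, `4R` = 0.45)
  structure(out,
            system = "dry",
            mmn_channel = "3Z",
            frontocentral = fc,
            eog_map = list(veog = c("EOGb", "1L"), heog = c("EOGl", "1LD")),
            mastoids = c("M1", "M2"))
}
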
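#' Residue hydropathy scale
#'
#' @param scale `"kd"` (Kyte-Doolittle, default), `"hw"` (Hopp-Woods) or
#'   `"eisenberg"` (Eisenberg consensus).
#' @return Named numeric vector over the alphabet; for Kyte-Doolittle,
#'   positive values are hydrophobic (range -4.5 to 4.5).
#' @export
hydropathy_scale <- function(scale = c("kd", "hw", "eisenberg")) {
  scale <- match.arg(scale)
  .HYDROPATHY_SCALES[[scale]]
}

# Deterministic quasi-uniform points on the unit sphere (golden-spiral
# lattice), the quadrature grid of the Shrake-Rupley point counting.
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Coarse solvent-accessible surface area (Shrake-Rupley)
#'
#' Computes per-residue SASA on a CA-coarse model: each residue is a
#' single sphere centred on its CA with a residue-type-specific effective
#' radius (derived from mean residue volumes).  A probe-inflated sphere of
#' quadrature points is placed on each residue and the accessible fraction
#' is the fraction of points not buried inside any neighbouring residue's
#' probe-inflated sphere.
#'
#' @param model A non-empty [structure_model()].
#' @param probe Probe radius in Angstrom (default 1.4, a water molecule).
#' @param n_points Quadrature points per sphere (default 960; at least
#'   100).
#' @return A list of class `"sasa_result"`: `per_residue` (numeric, Angstrom^2),
#'   `total`, `probe`, `n_points`, `radii`.
#' @examples
#' h <- generate_helix_coords(10)
#' shrake_rupley_sasa(h)$total
#' @export
shrake_rupley_sasa <- function(model, probe = 1.4, n_points = 960L) {
  stopifnot(inherits(model, "structure_model"))
  n <- length(model$resno)
  if (n == 0L) stop("model is empty", call. = FALSE)
  if (n_points < 100L) {
    stop("n_points must be at least 100 for usable precision",
         call. = FALSE)
  }
  radii <- unname(.AA_RADIUS[model$restype])
  radii[is.na(radii)] <- unname(.AA_RADIUS["X"])
  rext <- radii + probe
  pts <- sphere_points(n_points)
  xyz <- model$xyz
  # pairwise CA distances once; residues can only occlude within rext_i + rext_j
  dmat <- as.matrix(stats::dist(xyz))
  per <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(dmat[i, ] < rext[i] + rext & seq_len(n) != i)
    area_i <- 4 * pi * rext[i]^2
    if (length(nb) == 0L) {
      per[i] <- area_i
      next
    }
    p <- sweep(pts * rext[i], 2L, xyz[i, ], `+`)
    free <- rep(TRUE, n_points)
    for (j in nb) {
      if (!any(free)) break
      d2 <- (p[free, 1] - xyz[j, 1])^2 + (p[free, 2] - xyz[j, 2])^2 +
        (p[free, 3] - xyz[j, 3])^2
      free[free] <- d2 >= rext[j]^2
    }
    per[i] <- area_i * sum(free) / n_points
  }
  structure(list(per_residue = per, total = sum(per), probe = probe,
                 n_points = as.integer(n_points), radii = radii),
            class = "sasa_result")
}

#' @export
print.sasa_result <- function(x, ...) {
  cat(sprintf(
    "<sasa_result> %d residues, total %.1f A^2 (probe %.2f A, %d points)\n",
    length(x$per_residue), x$total, x$probe, x$n_points))
  invisible(x)
}

#' Surface-hydrophobicity report
#'
#' Quantifies how hydrophobic a structure's solvent-exposed surface is:
#' residues with SASA at or above `exposure_threshold` count as exposed,
#' and the surface hydrophobicity index is the SASA-weighted mean
#' hydropathy over exposed residues,
#' `sum(SASA_i * H_i) / sum(SASA_i)`.  On identical coordinates, QTY
#' substitution can only lower the index (each targeted substitution
#' strictly lowers the residue hydropathy), which turns the qualitative
#' "the variant surface is more hydrophilic" claim into a testable
#' inequality.
#'
#' @param model A [structure_model()].
#' @param sequence Optional sequence overriding the model's residue types
#'   (must match in length); used to score a variant sequence on native
#'   coordinates.
#' @param exposure_threshold SASA cutoff in Angstrom^2 for counting a residue
#'   as exposed (default 10).
#' @param scale Hydropathy scale name, see [hydropathy_scale()].
#' @param sasa Optional precomputed [shrake_rupley_sasa()] result (must
#'   match the model).
#' @param ... Passed to [shrake_rupley_sasa()].
#' @return A list of class `"hydrophobicity_report"`: `n_exposed`,
#'   `index` (`NA` when no residue is exposed), `per_class_sasa`
#'   (named fractions for hydrophobic / polar / charged), `total_sasa`,
#'   `exposure_threshold`, `scale`.
#' @export
surface_report <- function(model, sequence = NULL, exposure_threshold = 10,
                           scale = "kd", sasa = NULL, ...) {
  stopifnot(inherits(model, "structure_model"))
  restype <- model$restype
  if (!is.null(sequence)) {
    if (nchar(sequence) != length(model$resno)) {
      stop("sequence length does not match model residues", call. = FALSE)
    }
    restype <- check_alphabet(sequence)
  }
  if (is.null(sasa)) sasa <- shrake_rupley_sasa(model, ...)
  h <- hydropathy_scale(scale)[restype]
  exposed <- sasa$per_residue >= exposure_threshold
  idx <- if (any(exposed)) {
    sum(sasa$per_residue[exposed] * h[exposed]) /
      sum(sasa$per_residue[exposed])
  } else NA_real_
  classes <- rep("polar", length(restype))
  classes[restype %in% c("A", "V", "L", "I", "M", "F", "W", "C")] <-
    "hydrophobic"
  classes[restype %in% c("D", "E", "K", "R")] <- "charged"
  frac <- vapply(c("hydrophobic", "polar", "charged"), function(cl) {
    sum(sasa$per_residue[classes == cl]) / sasa$total
  }, numeric(1))
  structure(
    list(n_exposed = sum(exposed), index = idx, per_class_sasa = frac,
         total_sasa = sasa$total, exposure_threshold = exposure_threshold,
         scale = scale),
    class = "hydrophobicity_report")
}

#' @export
print.hydrophobicity_report <- function(x, ...) {
  cat(sprintf("<hydrophobicity_report> %d exposed residues\n", x$n_exposed))
  if (is.na(x$index)) {
    cat("  surface hydrophobicity index: undefined (no exposed residues)\n")
  } else {
    cat(sprintf("  surface hydrophobicity index (%s): %.3f\n",
                x$scale, x$index))
  }
  cat(sprintf("  SASA fractions: hydrophobic %.2f, polar %.2f, charged %.2f\n",
              x$per_class_sasa["hydrophobic"], x$per_class_sasa["polar"],
              x$per_class_sasa["charged"]))
  invisible(x)
}
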
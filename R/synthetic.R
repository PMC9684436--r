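# Synthetic-data generators: TM-architecture sequences, ideal helical CA
# traces, and rigid-transformed noisy decoys with known ground truth.
# Everything is a pure function of (spec, seed) so tests are reproducible.

#' Specification of a synthetic membrane protein
#'
#' Describes the alternating loop/TM-helix architecture of a multi-pass
#' membrane protein: `n_tm_segments` helices of `tm_length` residues,
#' separated (and flanked) by loops of `loop_length` residues.  A fraction
#' `livf_fraction_tm` of TM positions is drawn from the hydrophobic set
#' \{L, I, V, F\} — the residues targeted by the QTY code — so the default
#' of 0.5 yields TM variation percentages in the 44–55 % range typical of
#' solute-carrier transporters.  Loops are drawn from \{G,S,N,D,K,E,P\},
#' which contains no QTY-targeted residue, so any substitution outside a
#' TM segment is detectable.
#'
#' @param n_tm_segments Number of TM helices (>= 0; default 12, the common
#'   solute-carrier architecture).
#' @param tm_length Residues per TM helix (default 21, enough to span a
#'   lipid bilayer as an alpha helix).
#' @param loop_length Residues per loop (default 15).
#' @param livf_fraction_tm Fraction of TM positions drawn from
#'   \{L,I,V,F\} (default 0.5).
#' @param seed Integer random seed.
#' @return A list of class `"synthetic_protein_spec"`.
#' @export
synthetic_protein_spec <- function(n_tm_segments = 12L, tm_length = 21L,
                                   loop_length = 15L,
                                   livf_fraction_tm = 0.5, seed = 1L) {
  if (n_tm_segments < 0L || tm_length < 0L || loop_length < 0L) {
    stop("segment counts and lengths must be non-negative", call. = FALSE)
  }
  if (livf_fraction_tm < 0 || livf_fraction_tm > 1) {
    stop("livf_fraction_tm must lie in [0, 1]", call. = FALSE)
  }
  structure(
    list(n_tm_segments = as.integer(n_tm_segments),
         tm_length = as.integer(tm_length),
         loop_length = as.integer(loop_length),
         livf_fraction_tm = livf_fraction_tm,
         seed = as.integer(seed)),
    class = "synthetic_protein_spec")
}

.LOOP_AA <- c("G", "S", "N", "D", "K", "E", "P")
.LIVF <- c("L", "I", "V", "F")
# TM filler residues: helix-compatible, not targeted by the QTY code, no
# charged residues (charge conservation stays attributable to loops).
.TM_OTHER <- c("A", "G", "S", "T", "M", "W", "C", "N", "Q", "H", "Y")

#' Generate a synthetic membrane-protein record
#'
#' Builds the sequence loop–TM–loop–…–TM–loop described by the spec and
#' records the TM intervals (1-based, inclusive).
#'
#' @param spec A [synthetic_protein_spec()].
#' @param id Record identifier.
#' @return A [protein_record()] with TM annotations.
#' @examples
#' rec <- generate_membrane_protein(synthetic_protein_spec(seed = 7))
#' rec
#' @export
generate_membrane_protein <- function(spec, id = sprintf("SYN%04d",
                                                         spec$seed %% 1e4)) {
  stopifnot(inherits(spec, "synthetic_protein_spec"))
  with_seed(spec$seed, {
    parts <- character(0)
    tm <- matrix(integer(0), ncol = 2L)
    pos <- 0L
    loop <- function(n) paste(sample(.LOOP_AA, n, replace = TRUE),
                              collapse = "")
    parts <- c(parts, loop(spec$loop_length))
    pos <- spec$loop_length
    if (spec$n_tm_segments > 0L) {
      for (k in seq_len(spec$n_tm_segments)) {
        n <- spec$tm_length
        is_livf <- stats::runif(n) < spec$livf_fraction_tm
        seg <- ifelse(is_livf,
                      sample(.LIVF, n, replace = TRUE),
                      sample(.TM_OTHER, n, replace = TRUE))
        parts <- c(parts, paste(seg, collapse = ""))
        if (n > 0L) tm <- rbind(tm, c(pos + 1L, pos + n))
        pos <- pos + n
        parts <- c(parts, loop(spec$loop_length))
        pos <- pos + spec$loop_length
      }
    }
    protein_record(id, paste(parts, collapse = ""),
                   tm_segments = if (nrow(tm) > 0L) tm else NULL,
                   description = "synthetic multi-pass membrane protein")
  })
}

#' Ideal alpha-helix geometry
#'
#' @param rise_per_residue Rise along the helix axis per residue, Angstrom
#'   (default 1.5).
#' @param twist_per_residue Rotation about the axis per residue, degrees
#'   (default 100, i.e. 3.6 residues per turn).
#' @param radius Radius of the CA helix, Angstrom (default 2.3).
#' @return A list of class `"helix_geometry"`.
#' @export
helix_geometry <- function(rise_per_residue = 1.5, twist_per_residue = 100,
                           radius = 2.3) {
  if (rise_per_residue <= 0 || twist_per_residue <= 0 || radius <= 0) {
    stop("helix parameters must be strictly positive", call. = FALSE)
  }
  structure(list(rise_per_residue = rise_per_residue,
                 twist_per_residue = twist_per_residue,
                 radius = radius),
            class = "helix_geometry")
}

#' Generate an ideal helical CA trace
#'
#' Places `n_res` CA atoms on a regular helix (axis along z); all
#' consecutive CA–CA distances are exactly equal.
#'
#' @param n_res Number of residues (>= 2).
#' @param geom A [helix_geometry()].
#' @param sequence Optional one-letter sequence of length `n_res`
#'   (default poly-alanine).
#' @param id Model identifier.
#' @return A [structure_model()] with `source = "synthetic"`.
#' @examples
#' h <- generate_helix_coords(10)
#' dist(h$xyz[1:2, ])  # ~3.83 Angstrom chord
#' @export
generate_helix_coords <- function(n_res, geom = helix_geometry(),
                                  sequence = NULL, id = "helix") {
  if (n_res < 2L) stop("n_res must be at least 2", call. = FALSE)
  stopifnot(inherits(geom, "helix_geometry"))
  i <- seq_len(n_res) - 1L
  theta <- i * geom$twist_per_residue * pi / 180
  xyz <- cbind(geom$radius * cos(theta),
               geom$radius * sin(theta),
               i * geom$rise_per_residue)
  restype <- if (is.null(sequence)) rep("A", n_res) else {
    stopifnot(nchar(sequence) == n_res)
    aa_split(sequence)
  }
  structure_model(id, resno = seq_len(n_res), restype = restype,
                  xyz = xyz, source = "synthetic")
}

# Uniform random rotation over SO(3) via a normalized Gaussian quaternion.
random_rotation_matrix <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
    nrow = 3, byrow = TRUE)
}

#' Perturb a structure into a noisy, rigidly moved decoy
#'
#' Displaces each CA by isotropic Gaussian noise (standard deviation
#' `noise_sd` per coordinate) and then applies a random rigid rotation
#' (uniform over SO(3)) plus translation.  Residue identities are
#' unchanged.  After optimal superposition the expected RMSD against the
#' original is `noise_sd * sqrt(3)`, which makes the decoy a ground-truth
#' benchmark for the superposition module.
#'
#' @param model A non-empty [structure_model()].
#' @param noise_sd Per-coordinate noise standard deviation, Angstrom
#'   (>= 0).
#' @param seed Integer random seed.
#' @return A [structure_model()] with `source = "predicted"`.
#' @export
perturb_structure <- function(model, noise_sd, seed = 1L) {
  stopifnot(inherits(model, "structure_model"))
  if (length(model$resno) == 0L) stop("model is empty", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be non-negative", call. = FALSE)
  with_seed(seed, {
    n <- nrow(model$xyz)
    noisy <- model$xyz + matrix(stats::rnorm(3L * n, sd = noise_sd),
                                ncol = 3L)
    R <- random_rotation_matrix()
    t_vec <- stats::rnorm(3, sd = 10)
    xyz <- sweep(noisy %*% t(R), 2L, t_vec, `+`)
    structure_model(paste0(model$id, "_decoy"), resno = model$resno,
                    restype = model$restype, xyz = xyz,
                    chain = model$chain, ins = model$ins,
                    source = "predicted")
  })
}

#' Build a parallel helix bundle
#'
#' Places `n_helices` ideal helices parallel to z on a circle of radius
#' `bundle_radius`, giving a compact fixture with buried (inward-facing)
#' and exposed (outward-facing) residues for surface-area tests.
#'
#' @param n_helices Number of helices (default 4).
#' @param n_res Residues per helix (default 18).
#' @param bundle_radius Circle radius in Angstrom (default 8).
#' @param geom A [helix_geometry()].
#' @param sequence Optional sequence of length `n_helices * n_res`.
#' @param id Model identifier.
#' @return A [structure_model()] (residues numbered consecutively along
#'   the concatenated helices).
#' @export
make_helix_bundle <- function(n_helices = 4L, n_res = 18L,
                              bundle_radius = 8, geom = helix_geometry(),
                              sequence = NULL, id = "bundle") {
  stopifnot(n_helices >= 1L, n_res >= 2L)
  xyz_all <- NULL
  for (k in seq_len(n_helices) - 1L) {
    h <- generate_helix_coords(n_res, geom)
    phi <- 2 * pi * k / n_helices
    centre <- c(bundle_radius * cos(phi), bundle_radius * sin(phi), 0)
    xyz_all <- rbind(xyz_all, sweep(h$xyz, 2L, centre, `+`))
  }
  n_total <- n_helices * n_res
  restype <- if (is.null(sequence)) rep("A", n_total) else {
    stopifnot(nchar(sequence) == n_total)
    aa_split(sequence)
  }
  structure_model(id, resno = seq_len(n_total), restype = restype,
                  xyz = xyz_all, source = "synthetic")
}
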
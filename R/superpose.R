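#' Optimal rigid-body superposition (Kabsch algorithm)
#'
#' Fits the least-squares optimal proper rotation and translation moving
#' the mobile coordinate set `coords_b` onto the reference `coords_a`
#' (paired row-for-row), via the singular value decomposition of the
#' cross-covariance matrix with reflection correction.  This is the
#' algorithmic core behind every structure-alignment tool's final
#' superposition step.
#'
#' The fitted transform follows the convention
#' `transformed = coords %*% rotation + translation` (row vectors).
#'
#' @param coords_a Reference coordinates, n x 3 matrix (n >= 3).
#' @param coords_b Mobile coordinates, n x 3 matrix, paired with
#'   `coords_a`.
#' @return An object of class `"superposition"`; see
#'   [superpose_models()] for the full field list (here
#'   `rmsd_refined == rmsd_all` and all pairs are retained).
#' @examples
#' a <- matrix(rnorm(30), ncol = 3)
#' fit <- kabsch(a, a)   # identity transform, RMSD 0
#' fit$rmsd_all
#' @export
kabsch <- function(coords_a, coords_b) {
  a <- as.matrix(coords_a); b <- as.matrix(coords_b)
  stopifnot(ncol(a) == 3L, ncol(b) == 3L)
  n <- nrow(a)
  if (nrow(b) != n) stop("coordinate sets must be paired", call. = FALSE)
  if (n < 3L) {
    stop("superposition is underdetermined with fewer than 3 pairs",
         call. = FALSE)
  }
  ca <- colMeans(a); cb <- colMeans(b)
  a0 <- sweep(a, 2L, ca); b0 <- sweep(b, 2L, cb)
  sv <- svd(crossprod(b0, a0))  # H = t(b0) %*% a0
  if (sv$d[2] < 1e-10 * max(sv$d[1], 1)) {
    warning("degenerate (collinear) coordinate geometry; rotation is not unique")
  }
  d <- sign(det(sv$v %*% t(sv$u)))
  if (d == 0) d <- 1
  R <- sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
  t_vec <- ca - as.numeric(cb %*% R)
  moved <- sweep(b %*% R, 2L, t_vec, `+`)
  dev <- sqrt(rowSums((moved - a)^2))
  rmsd <- sqrt(mean(dev^2))
  structure(
    list(rotation = R, translation = t_vec,
         rmsd_all = rmsd, rmsd_refined = rmsd,
         n_pairs_initial = n, n_pairs_retained = n,
         retained = rep(TRUE, n), deviations = dev, cycles_run = 0L),
    class = "superposition")
}

#' @export
print.superposition <- function(x, ...) {
  cat("<superposition>\n")
  cat(sprintf("  pairs    : %d initial, %d retained (%d refinement cycle%s)\n",
              x$n_pairs_initial, x$n_pairs_retained, x$cycles_run,
              if (x$cycles_run == 1L) "" else "s"))
  cat(sprintf("  RMSD     : %.3f A (all pairs), %.3f A (retained)\n",
              x$rmsd_all, x$rmsd_refined))
  invisible(x)
}

#' @method coef superposition
#' @export
coef.superposition <- function(object, ...) {
  list(rotation = object$rotation, translation = object$translation)
}

#' @method residuals superposition
#' @export
residuals.superposition <- function(object, ...) {
  object$deviations
}

#' Apply a fitted superposition to coordinates
#'
#' @param object A `"superposition"` fit.
#' @param coords n x 3 matrix (default: nothing; coordinates must be
#'   supplied).
#' @param ... Unused.
#' @return The transformed n x 3 matrix.
#' @export
predict.superposition <- function(object, coords, ...) {
  coords <- as.matrix(coords)
  stopifnot(ncol(coords) == 3L)
  sweep(coords %*% object$rotation, 2L, object$translation, `+`)
}

#' Residue-trimming policy for superposition
#'
#' Structure comparisons of membrane transporters conventionally drop the
#' flexible N- and C-termini before superposing; this policy makes that
#' deterministic.  When a TM-annotated record is supplied to
#' [superpose_models()], residues outside the first/last TM segment are
#' dropped by default.
#'
#' @param drop_n_terminal Residues to drop from the N-terminus.
#' @param drop_c_terminal Residues to drop from the C-terminus.
#' @param drop_unpaired_loops Reserved flag: drop pairs whose sequence
#'   position lies outside every TM segment of the supplied record.
#' @return A list of class `"trim_policy"`.
#' @export
trim_policy <- function(drop_n_terminal = 0L, drop_c_terminal = 0L,
                        drop_unpaired_loops = FALSE) {
  if (drop_n_terminal < 0L || drop_c_terminal < 0L) {
    stop("trim counts must be non-negative", call. = FALSE)
  }
  structure(list(drop_n_terminal = as.integer(drop_n_terminal),
                 drop_c_terminal = as.integer(drop_c_terminal),
                 drop_unpaired_loops = isTRUE(drop_unpaired_loops)),
            class = "trim_policy")
}

#' Superpose two structure models with iterative outlier rejection
#'
#' Pairs the CA atoms of two models (through an explicit
#' [map_sequence_to_structure()] result, or by aligning their residue-type
#' strings when no map is given), applies the trimming policy, and runs
#' Kabsch superposition with iterative rejection: after each fit, pairs
#' deviating more than `reject_cutoff` are dropped and the fit repeated,
#' up to `cycles` times or until no pair is dropped.  This mirrors the
#' rejection-refinement behaviour of the common `align`-style tools, and
#' both the cycle-0 RMSD over all pairs (`rmsd_all`) and the final RMSD
#' over retained pairs (`rmsd_refined`) are reported so the protocol is
#' transparent.
#'
#' @param a Reference [structure_model()].
#' @param b Mobile [structure_model()].
#' @param map Optional `"seq_struct_map"` pairing positions of `a` (as
#'   sequence) to residues of `b`; default: identity-scored global
#'   alignment of the two residue-type strings.
#' @param trim A [trim_policy()].
#' @param tm_record Optional TM-annotated [protein_record()] matching `a`;
#'   when given, pairs outside the span from the first TM start to the
#'   last TM end are dropped (termini trimming).
#' @param cycles Maximum refinement cycles (default 5).
#' @param reject_cutoff Pair-deviation rejection cutoff in Angstrom
#'   (default 2.0).
#' @return An object of class `"superposition"` with fields `rotation`
#'   (3 x 3, determinant +1), `translation`, `rmsd_all`, `rmsd_refined`,
#'   `n_pairs_initial`, `n_pairs_retained`, `retained` (logical over
#'   initial pairs), `deviations` (over initial pairs, final transform),
#'   `cycles_run`.
#' @export
superpose_models <- function(a, b, map = NULL, trim = trim_policy(),
                             tm_record = NULL, cycles = 5L,
                             reject_cutoff = 2.0) {
  stopifnot(inherits(a, "structure_model"), inherits(b, "structure_model"),
            inherits(trim, "trim_policy"))
  if (is.null(map)) {
    rec_a <- protein_record(a$id, model_sequence(a))
    map <- map_sequence_to_structure(rec_a, b)
    idx_a <- map$pairs[, "seq_pos"]
  } else {
    stopifnot(inherits(map, "seq_struct_map"))
    idx_a <- map$pairs[, "seq_pos"]
  }
  idx_b <- map$pairs[, "struct_idx"]

  keep <- rep(TRUE, length(idx_a))
  if (trim$drop_n_terminal > 0L) keep[idx_a <= trim$drop_n_terminal] <- FALSE
  if (trim$drop_c_terminal > 0L) {
    keep[idx_a > length(a$resno) - trim$drop_c_terminal] <- FALSE
  }
  if (!is.null(tm_record)) {
    tm <- tm_record$tm_segments
    if (nrow(tm) > 0L) {
      span <- c(min(tm[, "start"]), max(tm[, "end"]))
      keep[idx_a < span[1] | idx_a > span[2]] <- FALSE
      if (trim$drop_unpaired_loops) {
        keep[keep] <- tm_mask(tm_record)[idx_a[keep]]
      }
    }
  }
  idx_a <- idx_a[keep]; idx_b <- idx_b[keep]
  if (length(idx_a) < 3L) {
    stop("fewer than 3 pairs left after trimming", call. = FALSE)
  }
  pa <- a$xyz[idx_a, , drop = FALSE]
  pb <- b$xyz[idx_b, , drop = FALSE]

  fit <- kabsch(pa, pb)
  rmsd_all <- fit$rmsd_all
  retained <- rep(TRUE, nrow(pa))
  cycles_run <- 0L
  for (cyc in seq_len(cycles)) {
    dev_retained <- fit$deviations
    drop <- dev_retained > reject_cutoff
    if (!any(drop)) break
    retained[retained][drop] <- FALSE
    if (sum(retained) < 3L) {
      stop("refinement collapse: fewer than 3 pairs survive the cutoff",
           call. = FALSE)
    }
    fit <- kabsch(pa[retained, , drop = FALSE],
                  pb[retained, , drop = FALSE])
    cycles_run <- cyc
  }
  dev_final <- sqrt(rowSums(
    (predict.superposition(fit, pb) - pa)^2))
  structure(
    list(rotation = fit$rotation, translation = fit$translation,
         rmsd_all = rmsd_all, rmsd_refined = fit$rmsd_all,
         n_pairs_initial = nrow(pa), n_pairs_retained = sum(retained),
         retained = retained, deviations = dev_final,
         cycles_run = cycles_run,
         pair_index = cbind(ref = idx_a, mobile = idx_b)),
    class = "superposition")
}
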
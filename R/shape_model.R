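#' Shape-model algebra: alignment, tangent projection, PCA
#'
#' The point-distribution model is built from corresponded lung shapes: every
#' training shape is centered, scaled to unit Frobenius norm, rotated into a
#' common frame by generalized Procrustes iteration, projected into the
#' tangent space at the mean, and summarized by PCA. A shape instance is then
#' `mean + P %*% b`, with the coefficient vector `b` constrained to plausible
#' ranges during segmentation.
#'
#' @name shape_model
NULL

make_shape_template <- function(n_between, n_slices, side = "right") {
  per_point <- 3L * (n_between - 1L)
  tibble::tibble(
    slice = rep(seq_len(n_slices), each = per_point),
    point = rep(seq_len(per_point), times = n_slices),
    arc = rep(rep(1:3, each = n_between - 1L), times = n_slices),
    x = 0, y = 0, z = rep(seq_len(n_slices), each = per_point) * 1.0
  ) -> df
  structure(df, n_between = n_between, n_slices = n_slices, side = side,
            class = c("lung_shape", class(tibble::tibble())))
}

#' Center a shape on its centroid
#'
#' @param X n x 3 matrix of shape points (or a `lung_shape`).
#' @return list with `X` (centered matrix) and `centroid` (length-3 vector).
#' @export
center_shape <- function(X) {
  if (inherits(X, "lung_shape")) X <- shape_points_matrix(X)
  cen <- colMeans(X)
  list(X = sweep(X, 2, cen), centroid = cen)
}

#' Frobenius shape size
#'
#' The Frobenius norm of a centered shape,
#' `Vol = sqrt(sum(x_i^2 + y_i^2 + z_i^2))`; dividing all coordinates by it
#' gives a unit-size shape, `|X| = 1`.
#'
#' @param X centered n x 3 matrix (or a `lung_shape`).
#' @return non-negative scalar.
#' @export
frobenius_volume <- function(X) {
  if (inherits(X, "lung_shape")) X <- shape_points_matrix(X)
  v <- sqrt(sum(X^2))
  if (v == 0) stop("degenerate shape: all points at the origin")
  v
}

#' Optimal rotation between two corresponded point sets
#'
#' The proper rotation `R` minimizing `sum |R x_i - y_i|^2`, from the SVD of
#' the 3x3 cross-covariance of corresponding points, with a determinant sign
#' correction so reflections are never returned.
#'
#' @param X,X_ref centered n x 3 matrices with corresponding rows.
#' @return list with `X` (rotated copy of `X`) and `R` (3 x 3 rotation).
#' @export
align_rotation <- function(X, X_ref) {
  if (inherits(X, "lung_shape")) X <- shape_points_matrix(X)
  if (inherits(X_ref, "lung_shape")) X_ref <- shape_points_matrix(X_ref)
  if (nrow(X) != nrow(X_ref)) stop("mismatched point counts")
  H <- crossprod(X, X_ref)      # 3x3
  sv <- svd(H)
  s <- c(1, 1, sign(det(sv$v %*% t(sv$u))))
  R <- sv$v %*% diag(s) %*% t(sv$u)
  list(X = X %*% t(R), R = R)
}

#' Generalized Procrustes alignment of a training set
#'
#' Every shape is centered and scaled to unit Frobenius norm; all shapes are
#' first rotated to the initial reference (the first shape of the list — a
#' deterministic stand-in for an arbitrary member of the set), then
#' iteratively to the current mean, recomputed each pass, until the sum of
#' squared distances to the mean drops below `d_stop` (default 1, in
#' unit-norm shape coordinates) or `max_iter` passes have run (warned).
#'
#' @param shapes list of `lung_shape`s (or n x 3 matrices) with identical
#'   point counts.
#' @param d_stop stopping threshold on `D = sum_i |X_i - mean|^2`.
#' @param max_iter iteration cap (default 50).
#' @return list with `aligned` (list of n x 3 matrices), `mean` (n x 3,
#'   unit-norm), `report` (tibble: `iteration`, `D`) and `template` (a
#'   `lung_shape` carrying the index structure, when inputs were shapes).
#' @export
procrustes_align <- function(shapes, d_stop = 1, max_iter = 50) {
  if (length(shapes) < 2L) stop("need at least 2 shapes to align")
  template <- if (inherits(shapes[[1]], "lung_shape")) shapes[[1]] else NULL
  mats <- lapply(shapes, function(s) {
    m <- if (inherits(s, "lung_shape")) shape_points_matrix(s) else s
    m <- center_shape(m)$X
    m / frobenius_volume(m)
  })
  np <- vapply(mats, nrow, integer(1))
  if (length(unique(np)) != 1L) stop("shapes have differing point counts")
  ref <- mats[[1]]
  mats <- lapply(mats, function(m) align_rotation(m, ref)$X)
  trace <- numeric(0)
  iter <- 0L
  repeat {
    iter <- iter + 1L
    mn <- Reduce(`+`, mats) / length(mats)
    mn <- mn / frobenius_volume(mn)
    mats <- lapply(mats, function(m) align_rotation(m, mn)$X)
    D <- sum(vapply(mats, function(m) sum((m - mn)^2), numeric(1)))
    trace <- c(trace, D)
    if (D < d_stop || iter >= max_iter) break
  }
  if (trace[length(trace)] >= d_stop)
    warning("Procrustes alignment stopped at iteration cap with D = ",
            signif(trace[length(trace)], 4))
  mn <- Reduce(`+`, mats) / length(mats)
  mn <- mn / frobenius_volume(mn)
  list(aligned = mats, mean = mn,
       report = tibble::tibble(iteration = seq_along(trace), D = trace),
       template = template)
}

#' Project aligned shapes into the tangent space at the mean
#'
#' Each aligned unit-norm shape is rescaled by the reciprocal of its inner
#' product with the mean, which linearizes the shape space around the mean
#' before PCA. After projection `X' . mean = |mean|^2` holds for every shape.
#'
#' @param X aligned n x 3 matrix (or `lung_shape`).
#' @param mean_shape the post-alignment mean (n x 3 matrix).
#' @return the projected n x 3 matrix.
#' @export
tangent_project <- function(X, mean_shape) {
  if (inherits(X, "lung_shape")) X <- shape_points_matrix(X)
  ip <- sum(X * mean_shape)
  if (ip <= 0)
    stop("non-positive inner product with the mean shape; alignment failed")
  X / ip
}

#' Fit the PCA point-distribution model
#'
#' Eigen-decomposition of the `1/m`-normalized covariance of the projected
#' training shapes, computed through the SVD of the centered (m x d) data
#' matrix (d is about 5000 while m is a few dozen, so the d x d covariance is
#' never formed). The smallest number of leading modes whose cumulative
#' variance reaches `variance_fraction` is retained; trailing modes — the
#' ones most affected by outliers or residual misalignment — are discarded.
#'
#' @param projected list of projected n x 3 matrices (from
#'   [tangent_project()]).
#' @param variance_fraction proportion of total variance to retain
#'   (default 0.95).
#' @param template optional `lung_shape` giving the index structure.
#' @param side `"left"` or `"right"` (stored on the model).
#' @return an `asm_model`: list with `mean` (length-d vector), `P` (d x t
#'   eigenvector matrix), `eigenvalues` (length t), `all_eigenvalues`,
#'   `t`, `variance_fraction` (achieved), `m`, `n_between`, `n_slices`,
#'   `side`, `schema_version`.
#' @export
fit_pca <- function(projected, variance_fraction = 0.95, template = NULL,
                    side = NULL) {
  m <- length(projected)
  if (m < 2L) stop("need at least 2 shapes for PCA")
  M <- t(vapply(projected, function(x) as.numeric(t(x)), # row-major x1,y1,z1,...
                numeric(3L * nrow(projected[[1]]))))
  mean_vec <- colMeans(M)
  Xc <- sweep(M, 2, mean_vec)
  sv <- svd(Xc, nu = 0)
  lambda <- sv$d^2 / m                    # 1/m covariance normalization
  total <- sum(lambda)
  if (total <= .Machine$double.eps * m) {
    warning("degenerate training set: zero total variance, retaining 0 modes")
    t_keep <- 0L
    achieved <- 1
  } else {
    cum <- cumsum(lambda) / total
    t_keep <- which(cum >= variance_fraction)[1]
    achieved <- cum[t_keep]
  }
  P <- if (t_keep > 0) sv$v[, seq_len(t_keep), drop = FALSE] else
    matrix(0, ncol(M), 0)
  nb <- if (!is.null(template)) attr(template, "n_between") else NA_integer_
  ns <- if (!is.null(template)) attr(template, "n_slices") else NA_integer_
  if (is.null(side) && !is.null(template)) side <- attr(template, "side")
  structure(
    list(mean = mean_vec, P = P,
         eigenvalues = lambda[seq_len(t_keep)], all_eigenvalues = lambda,
         t = t_keep, variance_fraction = achieved, m = m,
         n_between = nb, n_slices = ns, side = side %||% "right",
         schema_version = "spectasm-model-1"),
    class = "asm_model"
  )
}

#' Generate a shape instance from model coefficients
#'
#' `X = mean + P %*% b`, in the model (aligned, unit-size) frame.
#'
#' @param model an `asm_model`.
#' @param b coefficient vector of length `model$t`.
#' @return a `lung_shape` when the model carries an index structure,
#'   otherwise an n x 3 matrix.
#' @export
generate_shape <- function(model, b) {
  stopifnot(inherits(model, "asm_model"))
  if (length(b) != model$t)
    stop("coefficient vector has length ", length(b), ", model retains ",
         model$t, " modes")
  v <- model$mean + if (model$t > 0) as.numeric(model$P %*% b) else 0
  if (!is.na(model$n_between)) {
    vec_to_shape(v, make_shape_template(model$n_between, model$n_slices,
                                        model$side))
  } else {
    matrix(v, ncol = 3, byrow = TRUE)
  }
}

#' Project a shape onto the model basis
#'
#' `b = t(P) %*% (x - mean)` for a shape already expressed in the model frame.
#'
#' @param model an `asm_model`.
#' @param x shape as length-d vector, n x 3 matrix, or `lung_shape`.
#' @return numeric coefficient vector of length `model$t`.
#' @export
project_shape <- function(model, x) {
  if (inherits(x, "lung_shape")) x <- shape_to_vec(x)
  if (is.matrix(x)) x <- as.numeric(t(x))
  as.numeric(crossprod(model$P, x - model$mean))
}

#' Train left/right shape models from parameterized lung shapes
#'
#' Convenience wrapper: Procrustes alignment, tangent projection against the
#' post-alignment mean, PCA.
#'
#' @param shapes list of `lung_shape`s of one side.
#' @param variance_fraction retained variance proportion (default 0.95).
#' @param d_stop,max_iter passed to [procrustes_align()].
#' @return an `asm_model` with the alignment `report` attached as attribute
#'   `alignment`.
#' @export
train_shape_model <- function(shapes, variance_fraction = 0.95,
                              d_stop = 1, max_iter = 50) {
  al <- procrustes_align(shapes, d_stop = d_stop, max_iter = max_iter)
  proj <- lapply(al$aligned, tangent_project, mean_shape = al$mean)
  model <- fit_pca(proj, variance_fraction = variance_fraction,
                   template = al$template)
  attr(model, "alignment") <- al$report
  model
}

#' @export
print.asm_model <- function(x, ...) {
  cat(sprintf(
    "<asm_model> side %s: %d training shapes, %d/%d modes (%.1f%% variance), %d points\n",
    x$side, x$m, x$t, length(x$all_eigenvalues), 100 * x$variance_fraction,
    length(x$mean) / 3
  ))
  invisible(x)
}

#' Tidy a shape model: one row per retained eigenmode
#'
#' @param x an `asm_model`.
#' @param ... unused.
#' @return tibble with `mode`, `eigenvalue`, `prop_variance`,
#'   `cum_prop_variance`, `b_limit_paper` (the plausibility half-width
#'   `lambda * sqrt(2)`) and `b_limit_classic` (`3 * sqrt(lambda)`).
#' @export
tidy.asm_model <- function(x, ...) {
  total <- sum(x$all_eigenvalues)
  lam <- x$eigenvalues
  tibble::tibble(
    mode = seq_along(lam),
    eigenvalue = lam,
    prop_variance = lam / total,
    cum_prop_variance = cumsum(lam) / total,
    b_limit_paper = lam * sqrt(2),
    b_limit_classic = 3 * sqrt(lam)
  )
}

#' One-row model summary
#'
#' @param x an `asm_model`.
#' @param ... unused.
#' @return one-row tibble.
#' @export
glance.asm_model <- function(x, ...) {
  tibble::tibble(
    side = x$side, n_train = x$m, n_modes = x$t,
    n_points = length(x$mean) / 3,
    variance_fraction = x$variance_fraction,
    total_variance = sum(x$all_eigenvalues)
  )
}

#' Save or load a shape model
#'
#' The on-disk format is a single JSON document of named numeric arrays plus
#' scalar metadata (schema version, side, N, slice count, mode count,
#' variance fraction). Numbers are written at full precision, so a loaded
#' model reproduces [generate_shape()] outputs bit-identically.
#'
#' @param model an `asm_model`.
#' @param path file path (conventionally `.asm.json`).
#' @return `path` (save) or the restored `asm_model` (load).
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "asm_model"))
  # numeric arrays go in as base64-encoded little-endian float64 so the
  # round-trip is bit-exact regardless of decimal printing
  enc <- function(x) jsonlite::base64_enc(writeBin(as.numeric(x), raw(),
                                                   size = 8,
                                                   endian = "little"))
  payload <- list(
    schema_version = model$schema_version,
    side = model$side, m = model$m, t = model$t,
    n_between = model$n_between, n_slices = model$n_slices,
    variance_fraction = model$variance_fraction,
    array_encoding = "base64/float64-le",
    mean = enc(model$mean),
    eigenvalues = enc(model$eigenvalues),
    all_eigenvalues = enc(model$all_eigenvalues),
    P = enc(model$P), P_dim = dim(model$P)
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  payload <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                      error = function(e) stop("cannot parse model file ",
                                               path, ": ", conditionMessage(e)))
  if (is.null(payload$schema_version))
    stop("model schema error: no schema_version field in ", path)
  if (!identical(payload$schema_version, "spectasm-model-1"))
    stop("model schema version mismatch: found ", payload$schema_version,
         ", expected spectasm-model-1")
  dec <- function(s) {
    raw <- jsonlite::base64_dec(s)
    readBin(raw, "double", n = length(raw) / 8, size = 8, endian = "little")
  }
  structure(
    list(mean = dec(payload$mean),
         P = matrix(dec(payload$P), payload$P_dim[1], payload$P_dim[2]),
         eigenvalues = dec(payload$eigenvalues),
         all_eigenvalues = dec(payload$all_eigenvalues),
         t = as.integer(payload$t),
         variance_fraction = payload$variance_fraction,
         m = as.integer(payload$m),
         n_between = suppressWarnings(as.integer(payload$n_between)),
         n_slices = suppressWarnings(as.integer(payload$n_slices)),
         side = payload$side,
         schema_version = payload$schema_version),
    class = "asm_model"
  )
}
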
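# Synthetic subtomogram generator. Six structurally distinct
# macromolecule-like density phantoms (sphere, ellipsoid, cylinder,
# dumbbell, torus, cross) are rendered on a 32^3 grid, smoothed with a
# small Gaussian kernel to emulate band-limited density, randomly rotated
# and embedded in additive zero-mean Gaussian noise at a configurable
# signal-to-noise ratio (SNR = signal power / noise variance). Disjoint
# family sets provide the in-distribution and out-of-distribution classes.

phantom_families <- c("sphere", "ellipsoid", "cylinder", "dumbbell",
                      "torus", "cross")

#' Describe a density phantom
#'
#' @param family One of `"sphere"`, `"ellipsoid"`, `"cylinder"`,
#'   `"dumbbell"`, `"torus"`, `"cross"`.
#' @param size Named numeric vector of size parameters in voxels;
#'   defaults per family are chosen to fill roughly a third of the box.
#' @param amplitude Peak density of the noiseless phantom.
#' @param n Grid extent (default 32).
#' @return List of class `"phantom_spec"`.
#' @export
phantom_spec <- function(family, size = NULL, amplitude = 1, n = 32L) {
  family <- match.arg(family, phantom_families)
  defaults <- switch(family,
    sphere = c(radius = 6),
    ellipsoid = c(a = 9, b = 6, c = 3.5),
    cylinder = c(radius = 3.5, half_length = 9),
    dumbbell = c(radius = 4.5, separation = 6, neck = 2),
    torus = c(major = 7, minor = 2.5),
    cross = c(half_width = 2.2, half_length = 10))
  if (!is.null(size)) defaults[names(size)] <- size
  structure(list(family = family, size = defaults,
                 amplitude = amplitude, n = as.integer(n)),
            class = "phantom_spec")
}

phantom_extent <- function(spec) {
  s <- spec$size
  switch(spec$family,
    sphere = s[["radius"]],
    ellipsoid = max(s),
    cylinder = max(s[["radius"]], s[["half_length"]]),
    dumbbell = s[["separation"]] + s[["radius"]],
    torus = s[["major"]] + s[["minor"]],
    cross = s[["half_length"]])
}

# separable periodic Gaussian blur, sigma in voxels
smooth_volume <- function(x, sigma = 1, radius = 3L) {
  k <- stats::dnorm(-radius:radius, sd = sigma)
  k <- k / sum(k)
  n <- dim(x)[1L]
  K <- matrix(0, n, n)
  for (t in seq_along(k)) {
    off <- t - radius - 1L
    cols <- ((seq_len(n) - 1L + off) %% n) + 1L
    K[cbind(seq_len(n), cols)] <- K[cbind(seq_len(n), cols)] + k[t]
  }
  for (ax in 1:3) x <- dwt_apply_axis(x, K, ax)
  x
}

#' Render a noiseless phantom volume
#'
#' Evaluates the phantom's support on the centred grid, scales to the
#' requested amplitude and applies a small Gaussian blur, giving a
#' nonnegative band-limited density map that vanishes outside the
#' support.
#'
#' @param spec A [phantom_spec()].
#' @param smooth_sigma Gaussian blur width in voxels (default 1).
#' @return 3D array of dim `c(n, n, n)`.
#' @export
make_phantom <- function(spec, smooth_sigma = 1) {
  stopifnot(inherits(spec, "phantom_spec"))
  n <- spec$n
  if (phantom_extent(spec) > n / 2 - 2)
    stop("invalid spec: phantom support exceeds the box margin", call. = FALSE)
  g <- seq_len(n) - (n + 1) / 2
  X <- array(rep(g, times = n * n), c(n, n, n))
  Y <- aperm(X, c(2L, 1L, 3L))
  Z <- aperm(X, c(3L, 2L, 1L))
  s <- spec$size
  inside <- switch(spec$family,
    sphere = X^2 + Y^2 + Z^2 <= s[["radius"]]^2,
    ellipsoid = (X / s[["a"]])^2 + (Y / s[["b"]])^2 + (Z / s[["c"]])^2 <= 1,
    cylinder = X^2 + Y^2 <= s[["radius"]]^2 & abs(Z) <= s[["half_length"]],
    dumbbell = {
      d <- s[["separation"]]
      ((X - d)^2 + Y^2 + Z^2 <= s[["radius"]]^2) |
        ((X + d)^2 + Y^2 + Z^2 <= s[["radius"]]^2) |
        (Y^2 + Z^2 <= s[["neck"]]^2 & abs(X) <= d)
    },
    torus = (sqrt(X^2 + Y^2) - s[["major"]])^2 + Z^2 <= s[["minor"]]^2,
    cross = {
      hw <- s[["half_width"]]; hl <- s[["half_length"]]
      (abs(X) <= hl & abs(Y) <= hw & abs(Z) <= hw) |
        (abs(Y) <= hl & abs(X) <= hw & abs(Z) <= hw) |
        (abs(Z) <= hl & abs(X) <= hw & abs(Y) <= hw)
    })
  vol <- array(as.numeric(inside), dim = c(n, n, n)) * spec$amplitude
  if (smooth_sigma > 0) vol <- smooth_volume(vol, smooth_sigma)
  vol
}

#' The 24 orientation-preserving right-angle cube rotations
#'
#' @return A list of 24 rotation descriptors, each with the axis
#'   permutation `perm`, the per-axis `flip` signs and the corresponding
#'   3x3 rotation `matrix`. The first element is the identity.
#' @export
rightangle_rotations <- function() {
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  out <- list()
  for (p in perms) {
    P <- diag(3)[p, ]
    for (s1 in c(1, -1)) for (s2 in c(1, -1)) for (s3 in c(1, -1)) {
      S <- diag(c(s1, s2, s3))
      M <- S %*% P
      if (abs(det(M) - 1) < 1e-9)
        out[[length(out) + 1L]] <- list(perm = p, flip = c(s1, s2, s3),
                                        matrix = M)
    }
  }
  # put the identity first, keep the rest in construction order
  idx <- which(vapply(out, function(r) all(r$matrix == diag(3)), logical(1)))
  c(out[idx], out[-idx])
}

apply_rightangle <- function(x, rot) {
  y <- aperm(x, rot$perm)
  for (ax in 1:3) if (rot$flip[ax] < 0) {
    idx <- rev(seq_len(dim(y)[ax]))
    y <- switch(ax, y[idx, , , drop = FALSE], y[, idx, , drop = FALSE],
                y[, , idx, drop = FALSE])
  }
  y
}

#' Rotate a cubic volume by a random right-angle or continuous rotation
#'
#' Default mode draws one of the 24 proper right-angle cube rotations
#' uniformly (a pure voxel permutation, no interpolation). Continuous
#' mode draws a uniform random 3D rotation and resamples trilinearly
#' (voxels mapped outside the cube become zero). Uses the current RNG
#' state.
#'
#' @param x Cubic 3D array.
#' @param mode `"rightangle"` or `"continuous"`.
#' @return The rotated volume.
#' @export
random_rotation_augment <- function(x, mode = c("rightangle", "continuous")) {
  mode <- match.arg(mode)
  d <- dim(x)
  if (length(d) != 3L || length(unique(d)) != 1L)
    stop("invalid shape: right-angle rotation needs a cubic volume",
         call. = FALSE)
  if (mode == "rightangle") {
    rots <- rightangle_rotations()
    apply_rightangle(x, rots[[sample.int(24L, 1L)]])
  } else {
    rotate_volume(x, random_rotation_matrix())
  }
}

#' Draw a uniformly random 3D rotation matrix
#'
#' Quaternion method: a unit 4-vector of standard normals maps to a
#' uniform element of SO(3).
#'
#' @return 3x3 rotation matrix.
#' @export
random_rotation_matrix <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1L]; x <- q[2L]; y <- q[3L]; z <- q[4L]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

#' Rotate a volume by an arbitrary rotation matrix
#'
#' Trilinear resampling about the volume centre; samples falling outside
#' the box are zero.
#'
#' @param x 3D array.
#' @param R 3x3 rotation matrix (output coordinate = `R` applied to input
#'   coordinate).
#' @return Rotated array of the same shape.
#' @export
rotate_volume <- function(x, R) {
  d <- dim(x)
  ctr <- (d + 1) / 2
  g1 <- seq_len(d[1L]) - ctr[1L]
  g2 <- seq_len(d[2L]) - ctr[2L]
  g3 <- seq_len(d[3L]) - ctr[3L]
  P <- cbind(rep(g1, times = d[2L] * d[3L]),
             rep(rep(g2, each = d[1L]), times = d[3L]),
             rep(g3, each = d[1L] * d[2L]))
  Q <- P %*% R  # source coords = R^{-1} applied as right-multiplication
  Q <- sweep(Q, 2L, ctr, "+")
  f <- floor(Q)
  w <- Q - f
  out <- numeric(nrow(Q))
  for (b1 in 0:1) for (b2 in 0:1) for (b3 in 0:1) {
    i1 <- f[, 1L] + b1; i2 <- f[, 2L] + b2; i3 <- f[, 3L] + b3
    ok <- i1 >= 1 & i1 <= d[1L] & i2 >= 1 & i2 <= d[2L] & i3 >= 1 & i3 <= d[3L]
    wt <- (if (b1 == 1) w[, 1L] else 1 - w[, 1L]) *
          (if (b2 == 1) w[, 2L] else 1 - w[, 2L]) *
          (if (b3 == 1) w[, 3L] else 1 - w[, 3L])
    lin <- i1[ok] + (i2[ok] - 1) * d[1L] + (i3[ok] - 1) * d[1L] * d[2L]
    out[ok] <- out[ok] + wt[ok] * x[lin]
  }
  array(out, d)
}

#' Simulate one noisy subtomogram
#'
#' Rotates the phantom and adds zero-mean Gaussian noise with variance
#' `mean(signal^2) / snr`, so the realised signal-to-noise ratio matches
#' the target on average. Uses the current RNG state; seed beforehand for
#' reproducibility.
#'
#' @param spec A [phantom_spec()] (or a pre-rendered volume).
#' @param snr Target signal-to-noise ratio, `> 0` (power ratio).
#' @param rotation `NULL` for a random right-angle rotation, an integer
#'   `1..24` selecting one, `FALSE` for none, or a 3x3 matrix for a
#'   continuous rotation.
#' @param smooth_sigma Passed to [make_phantom()].
#' @return Noisy 3D volume.
#' @export
simulate_subtomogram <- function(spec, snr, rotation = NULL,
                                 smooth_sigma = 1) {
  if (!is.numeric(snr) || length(snr) != 1L || is.na(snr) || snr <= 0)
    stop("invalid parameter: snr must be a positive number", call. = FALSE)
  vol <- if (is.array(spec)) spec else make_phantom(spec, smooth_sigma)
  if (is.null(rotation)) {
    vol <- random_rotation_augment(vol)
  } else if (is.matrix(rotation)) {
    vol <- rotate_volume(vol, rotation)
  } else if (is.numeric(rotation)) {
    vol <- apply_rightangle(vol, rightangle_rotations()[[rotation]])
  }  # rotation = FALSE: leave unrotated
  sigma2 <- mean(vol^2) / snr
  vol + array(stats::rnorm(length(vol), sd = sqrt(sigma2)), dim(vol))
}

#' Generate a balanced ID/OOD phantom dataset
#'
#' Renders `n_per_class` noisy subtomograms for every in-distribution
#' family (split into train/validation/ID-test) and every
#' out-of-distribution family (all assigned to the OOD test split). ID
#' labels are the indices into `id_families`; OOD records carry label
#' `NA`. Fully reproducible from `seed`.
#'
#' @param id_families,ood_families Disjoint subsets of the six phantom
#'   family names.
#' @param n_per_class Samples per family.
#' @param snr Signal-to-noise ratio of every sample.
#' @param splits Length-3 fractions (train, validation, test) for ID
#'   families; must sum to 1.
#' @param seed Integer seed.
#' @param n Grid extent.
#' @return List with `volumes` (list of arrays) and `manifest` (a
#'   data.frame with `sample_id`, `family`, `label`, `split`, plus
#'   attributes `seed` and `snr`).
#' @export
make_dataset <- function(id_families, ood_families, n_per_class, snr,
                         splits = c(0.8, 0.1, 0.1), seed = 1L, n = 32L) {
  if (length(intersect(id_families, ood_families)) > 0L)
    stop("invalid config: ID and OOD families must be disjoint", call. = FALSE)
  stopifnot(n_per_class >= 1, abs(sum(splits) - 1) < 1e-9)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  volumes <- list()
  rows <- list()
  add <- function(fam, label, split_tags) {
    base <- make_phantom(phantom_spec(fam, n = n))  # rendered once per family
    for (i in seq_len(n_per_class)) {
      v <- simulate_subtomogram(base, snr)
      volumes[[length(volumes) + 1L]] <<- v
      rows[[length(rows) + 1L]] <<- data.frame(
        sample_id = sprintf("%s_%03d", fam, i), family = fam,
        label = label, split = split_tags[i], stringsAsFactors = FALSE)
    }
  }
  n_tr <- round(splits[1L] * n_per_class)
  n_va <- round(splits[2L] * n_per_class)
  id_tags <- c(rep("train", n_tr), rep("val", n_va),
               rep("test_id", n_per_class - n_tr - n_va))
  for (ci in seq_along(id_families)) add(id_families[ci], ci, id_tags)
  for (fam in ood_families) add(fam, NA_integer_,
                                rep("test_ood", n_per_class))
  manifest <- do.call(rbind, rows)
  attr(manifest, "seed") <- seed
  attr(manifest, "snr") <- snr
  list(volumes = volumes, manifest = manifest)
}
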
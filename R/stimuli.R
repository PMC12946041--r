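#' Generate a jittered octagon stimulus
#'
#' Constructs one octagon inscribed in a circle of radius `radius` (degrees
#' of visual angle). The base template is a regular octagon; each vertex is
#' perturbed by an angular jitter uniform on `[-jitter_deg, +jitter_deg]`
#' while its radial distance stays fixed, so no displayed shape is ever
#' perfectly regular.
#'
#' In the `"asymmetric"` condition all eight vertices are jittered
#' independently. In the `"symmetric"` condition two anchor vertices (one
#' from each reflection orbit of the template) are jittered and the other six
#' are produced by successive reflections across the object-frame vertical
#' and horizontal axes; the whole shape is then rotated by `rotation_deg`
#' (45 or 135), so the two orthogonal mirror axes appear at 45 deg and
#' 135 deg in display coordinates. Vertices are returned sorted by polar
#' angle so the contour is a simple polygon.
#'
#' @param condition `"symmetric"` or `"asymmetric"`.
#' @param rotation_deg Display rotation, 45 or 135.
#' @param jitter_deg Half-range of the angular jitter, in `[0, 22.5)`.
#' @param radius Circumradius in degrees of visual angle.
#' @param seed Optional integer seed; a fixed seed gives identical vertices.
#' @param anchor_random If `TRUE`, the two anchor template vertices are
#'   chosen at random among the representatives of each reflection orbit;
#'   if `FALSE` (default) the template vertices at 22.5 and 67.5 deg are
#'   used. The generated distribution is identical either way.
#' @return An object of class `octagon`: list with `vertices` (8 x 2 matrix,
#'   columns x/y), `condition`, `rotation_deg`, `anchor_angles_deg` (object
#'   frame, symmetric condition only), `seed`.
#' @examples
#' s <- make_octagon("symmetric", 45, seed = 1)
#' sqrt(rowSums(s$vertices^2)) # all 0.75
#' @export
make_octagon <- function(condition = c("symmetric", "asymmetric"),
                         rotation_deg = 45, jitter_deg = 20, radius = 0.75,
                         seed = NULL, anchor_random = FALSE) {
  condition <- match.arg(condition)
  if (!rotation_deg %in% c(45, 135)) {
    abort("`rotation_deg` must be 45 or 135", class = "spnlab_parameter_error")
  }
  if (jitter_deg < 0 || jitter_deg >= 22.5) {
    abort("`jitter_deg` must lie in [0, 22.5)", class = "spnlab_parameter_error")
  }
  assert_positive(radius, "radius")

  template <- 22.5 + 45 * (0:7) # degrees, object frame
  anchors <- NULL
  gen <- with_seed(seed, {
    if (condition == "asymmetric") {
      list(ang = sort((template + runif(8, -jitter_deg, jitter_deg)) %% 360),
           anchors = NULL)
    } else {
      # reflection orbits of the template under {id, reflect-V, reflect-H,
      # rotate-180}: {22.5, 157.5, 202.5, 337.5} and {67.5, 112.5, 247.5,
      # 292.5}; one anchor per orbit guarantees 8 distinct vertices
      repeat {
        a1 <- if (anchor_random) sample(c(22.5, 157.5, 202.5, 337.5), 1) else 22.5
        a2 <- if (anchor_random) sample(c(67.5, 112.5, 247.5, 292.5), 1) else 67.5
        a1 <- a1 + runif(1, -jitter_deg, jitter_deg)
        a2 <- a2 + runif(1, -jitter_deg, jitter_deg)
        # orbit of angle a: {a, 180 - a (reflect vertical), -a (reflect
        # horizontal), 180 + a (both)}
        ang <- c(a1, 180 - a1, -a1, 180 + a1,
                 a2, 180 - a2, -a2, 180 + a2) %% 360
        gaps <- diff(c(sort(ang), min(ang) + 360)) # circular gaps
        if (min(gaps) > 1e-9) break # reject coincident vertices
      }
      list(ang = sort(ang), anchors = c(a1, a2) %% 360)
    }
  })
  ang <- gen$ang
  anchors <- gen$anchors
  disp <- (ang + rotation_deg) %% 360
  rad <- disp * pi / 180
  vertices <- cbind(x = radius * cos(rad), y = radius * sin(rad))
  ord <- order(atan2(vertices[, 2], vertices[, 1]))
  structure(
    list(vertices = vertices[ord, , drop = FALSE], condition = condition,
         rotation_deg = rotation_deg, anchor_angles_deg = anchors,
         radius = radius, seed = seed),
    class = "octagon"
  )
}

#' @export
print.octagon <- function(x, ...) {
  cat(sprintf("<octagon> %s, rotation %g deg, radius %g\n",
              x$condition, x$rotation_deg, x$radius))
  invisible(x)
}

octagon_vertices <- function(stimulus) {
  if (inherits(stimulus, "octagon")) stimulus$vertices else as.matrix(stimulus)
}

#' Test a point set for mirror symmetry about an axis
#'
#' Reflects every vertex about the axis through the origin at `axis_deg` and
#' checks whether the reflected set matches the original set within `tol`
#' under a bijective nearest-point matching.
#'
#' @param stimulus An `octagon` or an n x 2 matrix of points.
#' @param axis_deg Axis angle in degrees (counter-clockwise from screen
#'   right).
#' @param tol Matching tolerance (same units as the vertices).
#' @return `TRUE` or `FALSE`.
#' @export
is_mirror_symmetric <- function(stimulus, axis_deg, tol = 1e-6) {
  assert_positive(tol, "tol")
  v <- octagon_vertices(stimulus)
  a <- axis_deg * pi / 180
  # reflection about axis at angle a: rotation by -a, flip y, rotate back
  refl <- matrix(c(cos(2 * a), sin(2 * a), sin(2 * a), -cos(2 * a)), 2, 2)
  w <- v %*% refl
  n <- nrow(v)
  # bijective nearest-point matching (greedy is exact here because a valid
  # matching has all distances < tol while distinct vertices are far apart)
  used <- rep(FALSE, n)
  for (i in seq_len(n)) {
    d2 <- rowSums((v - matrix(w[i, ], n, 2, byrow = TRUE))^2)
    d2[used] <- Inf
    j <- which.min(d2)
    if (sqrt(d2[j]) > tol) return(FALSE)
    used[j] <- TRUE
  }
  TRUE
}

#' Principal elongation axis of a stimulus
#'
#' Eigen-decomposition of the vertex second-moment tensor about the
#' centroid. The principal axis is the eigenvector with the larger
#' eigenvalue; anisotropy is the eigenvalue ratio (larger/smaller). For an
#' isotropic tensor (ratio within 1e-9 of 1) the axis is undefined.
#'
#' @param stimulus An `octagon` or an n x 2 matrix of points.
#' @return List with `axis_deg` (in `[0, 180)`, `NA` when undefined),
#'   `anisotropy` (>= 1), and `defined` (logical).
#' @export
elongation_axis <- function(stimulus) {
  v <- octagon_vertices(stimulus)
  if (nrow(v) < 2 || all(apply(v, 2, function(c) max(c) - min(c)) < 1e-12)) {
    abort("vertices are coincident; elongation undefined",
          class = "spnlab_parameter_error")
  }
  c0 <- sweep(v, 2, colMeans(v))
  M <- crossprod(c0) / nrow(v)
  e <- eigen(M, symmetric = TRUE)
  ratio <- e$values[1] / e$values[2]
  if (!is.finite(ratio) || abs(ratio - 1) < 1e-9) {
    return(list(axis_deg = NA_real_, anisotropy = 1, defined = FALSE))
  }
  ax <- atan2(e$vectors[2, 1], e$vectors[1, 1]) * 180 / pi
  list(axis_deg = ax %% 180, anisotropy = ratio, defined = TRUE)
}

#' Perimeter and enclosed area of a stimulus polygon
#'
#' Shoelace formula on the angle-ordered vertex contour.
#'
#' @param stimulus An `octagon` or an n x 2 matrix of points (in contour
#'   order).
#' @return List with `perimeter` and `area`.
#' @export
polygon_metrics <- function(stimulus) {
  v <- octagon_vertices(stimulus)
  n <- nrow(v)
  nxt <- c(2:n, 1)
  per <- sum(sqrt(rowSums((v[nxt, ] - v)^2)))
  area <- abs(sum(v[, 1] * v[nxt, 2] - v[nxt, 1] * v[, 2])) / 2
  list(perimeter = per, area = area)
}

#' Generate a batch of octagon stimuli as a tibble
#'
#' @param n Number of stimuli.
#' @param condition,rotation_deg,jitter_deg,radius,anchor_random Passed to
#'   [make_octagon()]; `rotation_deg = NULL` alternates 45/135 at random.
#' @param seed Master seed; stimulus i uses a derived substream.
#' @return Tibble with one row per stimulus: `id`, `condition`,
#'   `rotation_deg`, `stimulus` (list column of `octagon` objects).
#' @export
make_octagons <- function(n, condition = "symmetric", rotation_deg = NULL,
                          jitter_deg = 20, radius = 0.75, seed = 1,
                          anchor_random = FALSE) {
  rots <- if (is.null(rotation_deg)) {
    with_seed(substream_seed(seed, 0), sample(c(45, 135), n, replace = TRUE))
  } else rep(rotation_deg, n)
  stims <- purrr::map(seq_len(n), function(i) {
    make_octagon(condition, rots[i], jitter_deg, radius,
                 seed = substream_seed(seed, i), anchor_random = anchor_random)
  })
  tibble::tibble(id = seq_len(n), condition = condition,
                 rotation_deg = rots, stimulus = stims)
}

#' Serialize a stimulus to a JSON record
#'
#' @param stimulus An `octagon`.
#' @param path Optional output file; if `NULL` the JSON string is returned.
#' @return JSON string (invisibly if written to file).
#' @export
write_octagon <- function(stimulus, path = NULL) {
  rec <- list(condition = stimulus$condition,
              rotation_deg = stimulus$rotation_deg,
              seed = stimulus$seed,
              vertices = unname(apply(stimulus$vertices, 1, as.numeric,
                                      simplify = FALSE)))
  js <- jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
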
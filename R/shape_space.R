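#' Shape-space lattices and the binding geometry
#'
#' Receptors (BCR, TCR) and ligands (antigens, MHCII-presented peptides) are
#' represented as points of a discrete planar lattice: the "antigen lattice"
#' for BCR/antigen shapes and the "peptide lattice" for TCR/peptide shapes.
#' A point `(x, y)` has `x` in `0..N` (the horizontal binding-profile
#' feature) and `y` in `-N/2..N/2` (vertical feature; positive values encode
#' convexity, negative values concavity). A receptor binds the mirror image
#' `(x, -y)` of a ligand perfectly; affinity decays with the Chebyshev
#' (l-infinity) distance from that mirror image.
#'
#' Shape points are length-two integer vectors `c(x, y)` or, vectorised,
#' two-column matrices with one point per row.
#'
#' @param N lattice size (default 1000). Must be an even integer `>= 2` so
#'   that `N/2` is integral.
#' @return `shape_lattice()` returns a list with elements `N`, `xlim`,
#'   `ylim` describing the closed coordinate bounds.
#' @examples
#' lat <- shape_lattice(1000)
#' linf_dist(c(550, 300), c(850, 150))
#' mirror_shape(c(700, -200))
#' binds_within(c(550, -300), c(550, 300), 0)
#' @export
shape_lattice <- function(N = 1000) {
  if (length(N) != 1L || !is.finite(N) || N < 2 || N %% 2 != 0)
    stop("lattice size N must be a single even integer >= 2", call. = FALSE)
  N <- as.integer(N)
  list(N = N, xlim = c(0L, N), ylim = c(-N %/% 2L, N %/% 2L))
}

as_shape_matrix <- function(z) {
  if (is.matrix(z)) {
    if (ncol(z) != 2L) stop("shape matrix must have two columns", call. = FALSE)
    z
  } else {
    if (length(z) != 2L) stop("a shape point is a length-2 vector c(x, y)", call. = FALSE)
    matrix(z, ncol = 2L)
  }
}

#' @rdname shape_lattice
#' @param z,z1,z2 shape points (length-2 vectors or two-column matrices;
#'   matrices are recycled row-wise against each other).
#' @param lattice optional lattice (from [shape_lattice()]); when supplied,
#'   points are checked against its bounds.
#' @return `linf_dist()` returns the nonnegative integer Chebyshev distance
#'   `max(|x2 - x1|, |y2 - y1|)`, vectorised over rows.
#' @export
linf_dist <- function(z1, z2, lattice = NULL) {
  a <- as_shape_matrix(z1); b <- as_shape_matrix(z2)
  if (!is.null(lattice)) {
    check_on_lattice(a, lattice)
    check_on_lattice(b, lattice)
  }
  d <- pmax(abs(b[, 1L] - a[, 1L]), abs(b[, 2L] - a[, 2L]))
  as.integer(d)
}

check_on_lattice <- function(z, lattice) {
  z <- as_shape_matrix(z)
  ok <- z[, 1L] >= lattice$xlim[1L] & z[, 1L] <= lattice$xlim[2L] &
    z[, 2L] >= lattice$ylim[1L] & z[, 2L] <= lattice$ylim[2L]
  if (!all(ok)) stop("shape point off lattice", call. = FALSE)
  invisible(TRUE)
}

#' @rdname shape_lattice
#' @return `mirror_shape()` returns the mirror image `(x, -y)`; it is an
#'   involution, and a receptor equal to `mirror_shape(ligand)` is perfectly
#'   complementary to that ligand.
#' @export
mirror_shape <- function(z) {
  m <- as_shape_matrix(z)
  m[, 2L] <- -m[, 2L]
  if (is.matrix(z)) m else m[1L, ]
}

#' @rdname shape_lattice
#' @param receptor,ligand shape points; the receptor is tested against the
#'   mirror image of the ligand.
#' @param radius nonnegative binding radius in lattice units.
#' @return `binds_within()` returns `TRUE` where
#'   `linf_dist(receptor, mirror_shape(ligand)) <= radius`.
#' @export
binds_within <- function(receptor, ligand, radius) {
  if (any(radius < 0)) stop("binding radius must be nonnegative", call. = FALSE)
  linf_dist(receptor, mirror_shape(as_shape_matrix(ligand))) <= radius
}

#' @rdname shape_lattice
#' @param n number of points to draw.
#' @return `random_shape()` returns an `n x 2` integer matrix of points drawn
#'   uniformly over the `(N + 1) x (N + 1)` grid, using R's global RNG (so
#'   draws are reproducible under [set.seed()]).
#' @export
random_shape <- function(n = 1L, N = 1000L) {
  lat <- shape_lattice(N)
  cbind(
    x = sample.int(lat$N + 1L, n, replace = TRUE) - 1L,
    y = sample.int(lat$N + 1L, n, replace = TRUE) - 1L - lat$N %/% 2L
  )
}

#' Write a shape-space snapshot as TSV
#'
#' A snapshot records, at one time point, the receptor/antigen content of the
#' two lattices as rows `kind, x, y, count` with `kind` one of `TCR`, `BCR`,
#' `self`, `foreign`. Snapshots are collected by [simulate_immune()] at the
#' times requested via the `snapshot_at` parameter.
#'
#' @param snapshot a data frame with columns `kind`, `x`, `y`, `count` (one
#'   element of the `snapshots` list of a simulation).
#' @param file path of the TSV file to write.
#' @return the file path, invisibly.
#' @export
write_snapshot <- function(snapshot, file) {
  stopifnot(all(c("kind", "x", "y", "count") %in% names(snapshot)))
  utils::write.table(snapshot[, c("kind", "x", "y", "count")], file,
    sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
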
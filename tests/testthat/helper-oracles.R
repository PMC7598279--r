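# Independent brute-force oracles, deliberately written with different
# formulas than the package internals.

# Total surface area via Heron's formula, one face at a time.
brute_area <- function(mesh) {
  v <- mesh$vertices
  total <- 0
  for (i in seq_len(nrow(mesh$faces))) {
    f <- mesh$faces[i, ]
    a <- sqrt(sum((v[f[1], ] - v[f[2], ])^2))
    b <- sqrt(sum((v[f[2], ] - v[f[3], ])^2))
    c_ <- sqrt(sum((v[f[3], ] - v[f[1], ])^2))
    s <- (a + b + c_) / 2
    total <- total + sqrt(max(s * (s - a) * (s - b) * (s - c_), 0))
  }
  total
}

# Volume of a tetrahedron given its 4 corner points (closed form).
brute_tetra_volume <- function(pts) {
  abs(det(rbind(pts[2, ] - pts[1, ], pts[3, ] - pts[1, ],
                pts[4, ] - pts[1, ]))) / 6
}

# A tetrahedron as a closed, outward-oriented tri_mesh.
random_tetra <- function() {
  repeat {
    pts <- matrix(stats::runif(12, -1, 1), 4, 3)
    v6 <- det(rbind(pts[2, ] - pts[1, ], pts[3, ] - pts[1, ],
                    pts[4, ] - pts[1, ]))
    if (abs(v6) > 1e-3) break
  }
  faces <- rbind(c(1, 3, 2), c(1, 2, 4), c(2, 3, 4), c(1, 4, 3))
  if (v6 > 0) faces <- faces[, c(1, 3, 2)]
  list(mesh = tri_mesh(pts, faces, clean = FALSE), pts = pts)
}

# A random triangle soup (open mesh) for area checks.
random_soup <- function(n_tri = 5) {
  pts <- matrix(stats::runif(9 * n_tri, -1, 1), ncol = 3)
  tri_mesh(pts, matrix(seq_len(3 * n_tri), ncol = 3, byrow = TRUE),
           clean = FALSE)
}

expect_rel <- function(actual, expected, tol) {
  expect_lt(abs(actual / expected - 1), tol)
}
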
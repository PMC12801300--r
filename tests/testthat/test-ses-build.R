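# brute-force probe-placement check for a pair: sample the contact circle
# finely and ask whether any probe position clears all other inflated atoms
brute_pair_edge <- function(atoms, i, j, probe, n_ang = 3600L) {
  R <- atoms$radii + probe
  ci <- atoms$centers[i, ]; cj <- atoms$centers[j, ]
  dvec <- cj - ci; d <- sqrt(sum(dvec^2))
  if (d >= R[i] + R[j] || d <= abs(R[i] - R[j])) return(FALSE)
  u <- dvec / d
  x <- (d^2 + R[i]^2 - R[j]^2) / (2 * d)
  rho <- sqrt(R[i]^2 - x^2)
  ref <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- ref - sum(ref * u) * u; e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(u[2] * e1[3] - u[3] * e1[2], u[3] * e1[1] - u[1] * e1[3],
          u[1] * e1[2] - u[2] * e1[1])
  q <- ci + x * u
  ang <- 2 * pi * (0:(n_ang - 1)) / n_ang
  others <- setdiff(seq_len(atoms$count), c(i, j))
  for (a in ang) {
    pc <- q + rho * (cos(a) * e1 + sin(a) * e2)
    ok <- TRUE
    for (k in others)
      if (sqrt(sum((pc - atoms$centers[k, ])^2)) < R[k]) { ok <- FALSE; break }
    if (ok) return(TRUE)
  }
  FALSE
}

test_that("contact edges exist exactly when a tangent probe fits", {
  one <- make_fixture("single_atom")$atoms
  cpx1 <- build_alpha_complex(one, 1.4)
  expect_equal(nrow(cpx1$edges), 0L)
  expect_equal(nrow(cpx1$triangles), 0L)

  near <- atom_set(rbind(c(0, 0, 0), c(3, 0, 0)), c(1.5, 1.5))
  expect_true(brute_pair_edge(near, 1, 2, 1.4))
  expect_equal(nrow(build_alpha_complex(near, 1.4)$edges), 1L)

  far <- atom_set(rbind(c(0, 0, 0), c(6, 0, 0)), c(1.5, 1.5))
  expect_false(brute_pair_edge(far, 1, 2, 1.4))
  expect_equal(nrow(build_alpha_complex(far, 1.4)$edges), 0L)

  # occluded edge: a third atom sitting on the contact circle blocks it
  blocker_pos <- c(1.5, sqrt((1.5 + 1.4)^2 - 1.5^2), 0)
  tri <- atom_set(rbind(near$centers, blocker_pos + c(0, 0.2, 0)), c(1.5, 1.5, 6))
  expect_false(brute_pair_edge(tri, 1, 2, 1.4))
  cpx <- build_alpha_complex(tri, 1.4)
  expect_false(any(cpx$edges[, 1] == 1 & cpx$edges[, 2] == 2))
})

test_that("coincident atoms are resolved deterministically, not fatally", {
  dup <- atom_set(rbind(c(0, 0, 0), c(0, 0, 0), c(3, 0, 0)), c(1.5, 1.5, 1.5))
  c1 <- build_alpha_complex(dup, 1.4)
  c2 <- build_alpha_complex(dup, 1.4)
  expect_identical(c1$edges, c2$edges)
})

test_that("patch taxonomy follows the complex", {
  one <- make_fixture("single_atom")$atoms
  ps1 <- build_patches(build_alpha_complex(one, 1.4), one, 1.4)
  expect_equal(unname(patch_census(ps1)), c(1L, 0L, 0L))
  expect_equal(ps1$patches[[1]]$trim$bbox, rbind(c(-2, -2, -2), c(2, 2, 2)))

  pair <- make_fixture("pair")
  psp <- build_patches(build_alpha_complex(pair$atoms, 1.4), pair$atoms, 1.4)
  expect_equal(patch_census(psp), pair$expected$census)

  trip <- make_fixture("triple")
  pst <- build_patches(build_alpha_complex(trip$atoms, 1.4), trip$atoms, 1.4)
  expect_equal(patch_census(pst), trip$expected$census)
  # tripod tangency: both probe centres equidistant (r+rp) from all atoms
  conc <- Filter(function(p) p$kind == "concave_sphere", pst$patches)
  expect_equal(length(conc), 2L)
  for (p in conc)
    for (i in 1:3)
      expect_equal(sqrt(sum((p$center - trip$atoms$centers[i, ])^2)), 2.9,
                   tolerance = 1e-9)

  # probe 0: pure van der Waals sphere patches
  ps0 <- build_patches(build_alpha_complex(pair$atoms, 0), pair$atoms, 0)
  expect_equal(unname(patch_census(ps0)), c(2L, 0L, 0L))
})

test_that("patch geometry stays inside the trim bbox", {
  fx <- make_fixture("triple")
  ps <- build_patches(build_alpha_complex(fx$atoms, 1.4), fx$atoms, 1.4)
  g <- ray_grid(fx$atoms, 2, 1.4)
  rs <- quiet(trace_patches(ps, g))
  for (f in rs$families) {
    ax <- sesray:::.cross_axes[[f$dir]]
    for (id in seq_along(f$rays)) {
      m <- f$rays[[id]]
      if (!nrow(m)) next
      u <- (id - 1L) %% f$npix[1]; v <- (id - 1L) %/% f$npix[1]
      o <- sesray:::.ray_geom(g, f$dir, u, v, f$class)$origin
      for (r in seq_len(nrow(m))) {
        pt <- o; pt[f$dir] <- pt[f$dir] + m[r, 1]
        bbox <- ps$patches[[m[r, 5]]]$trim$bbox
        expect_true(all(pt >= bbox[1, ] - 1e-9 & pt <= bbox[2, ] + 1e-9))
      }
    }
  }
})

test_that("trimming-solid vertices satisfy its half-spaces", {
  fx <- make_fixture("ring_pocket")
  ps <- build_patches(build_alpha_complex(fx$atoms, 1.4), fx$atoms, 1.4)
  for (p in ps$patches) {
    hs <- p$trim$half_spaces
    for (r in seq_len(nrow(hs)))
      expect_true(all(p$trim$vertices %*% hs[r, 1:3] <= hs[r, 4] + 1e-9))
    expect_true(all(p$trim$vertices >= matrix(p$trim$bbox[1, ],
                                              nrow(p$trim$vertices), 3,
                                              byrow = TRUE) - 1e-9))
  }
})

test_that("the complex is invariant under atom relabeling", {
  fx <- make_fixture("random_cluster", n = 15, seed = 3)
  perm <- c(7, 3, 15, 1, 9, 12, 2, 14, 5, 11, 8, 4, 13, 6, 10)
  shuffled <- atom_set(fx$atoms$centers[perm, ], fx$atoms$radii[perm])
  ps1 <- build_patches(build_alpha_complex(fx$atoms, 1.4), fx$atoms, 1.4)
  ps2 <- build_patches(build_alpha_complex(shuffled, 1.4), shuffled, 1.4)
  sig <- function(ps) {
    m <- t(vapply(ps$patches, function(p)
      c(match(p$kind, c("convex_sphere", "torus", "concave_sphere")),
        round(p$center, 6), round(p$radius, 6)), numeric(5)))
    m[do.call(order, as.data.frame(m)), ]
  }
  expect_equal(sig(ps1), sig(ps2))
})

test_that("slab boundaries balance atom counts and respect the 12 A minimum", {
  set.seed(1)
  a <- atom_set(cbind(runif(100, -5, 5), runif(100, 0, 100), runif(100, -5, 5)),
                rep(1.5, 100))
  p <- slab_partition(a, 4, 12)
  expect_equal(p$n_slabs, 4L)
  counts <- vapply(p$per_slab_atom_ids, length, integer(1))
  expect_true(all(abs(counts - 25) <= 2))
  expect_identical(sort(unlist(p$per_slab_atom_ids)), 1:100)
  expect_true(all(diff(p$boundaries) >= 12 - 1e-9))
  expect_true(all(diff(p$boundaries) > 0))

  # Y extent 30 with 8 requested slabs: capped to floor(30/12) = 2
  b <- atom_set(cbind(0, seq(0, 30, length.out = 10), 0), rep(1.5, 10))
  expect_equal(slab_partition(b, 8, 12)$n_slabs, 2L)

  # requested 1: everything in one slab, no halos
  p1 <- slab_partition(a, 1, 12)
  expect_equal(p1$n_slabs, 1L)
  expect_equal(p1$per_slab_atom_ids[[1]], seq_len(a$count))
  expect_equal(p1$per_slab_halo_ids[[1]], integer(0))

  # halo atoms sit within `halo` of a boundary but outside the slab
  for (s in 1:4) {
    lo <- p$boundaries[s]; hi <- p$boundaries[s + 1]
    for (i in p$per_slab_halo_ids[[s]]) {
      y <- a$centers[i, 2]
      expect_true(y < lo || y >= hi)
      expect_true(y >= lo - 12 && y < hi + 12)
    }
  }
})

test_that("dedup keeps each patch exactly once, by trim bottom vertex", {
  # rule application: bottom vertex at Y=4.9 with slab [5,17) is discarded
  fake_patch <- function(ymin) {
    structure(list(kind = "convex_sphere", center = c(0, ymin + 1, 0),
                   radius = 1, trim = list(
                     vertices = rbind(c(0, ymin, 0), c(0, ymin + 2, 0)),
                     half_spaces = matrix(0, 0, 4),
                     bbox = rbind(c(-1, ymin, -1), c(1, ymin + 2, 1))),
                   id = 1L), class = "ses_patch")
  }
  part <- list(n_slabs = 2L, boundaries = c(5, 17, 30), halo = 12)
  ps_a <- structure(list(patches = list(fake_patch(4.9)), probe_radius = 1.4),
                    class = "patch_set")
  ps_b <- structure(list(patches = list(), probe_radius = 1.4),
                    class = "patch_set")
  # slab 1 interval is open below: 4.9 belongs to slab 1 (not discarded there)
  kept <- dedup_patches(list(ps_a, ps_b), part)
  expect_equal(length(kept$patches), 1L)
  # the same patch offered by slab 2 is discarded (4.9 < 17)
  kept2 <- dedup_patches(list(ps_b, ps_a), part)
  expect_equal(length(kept2$patches), 0L)

  # N = 1 is the identity
  fx <- make_fixture("pair")
  ps <- build_patches(build_alpha_complex(fx$atoms, 1.4), fx$atoms, 1.4)
  part1 <- slab_partition(fx$atoms, 1, 12)
  expect_equal(length(dedup_patches(list(ps), part1)$patches),
               length(ps$patches))
})

test_that("multi-slab builds reproduce the single-slab patch multiset", {
  set.seed(3)
  yc <- seq(0, 58.5, length.out = 40)
  chain <- atom_set(cbind(rnorm(40, 0, 0.8), yc, rnorm(40, 0, 0.8)),
                    runif(40, 1.3, 1.8))
  sig <- function(ps) {
    m <- t(vapply(ps$patches, function(p)
      c(match(p$kind, c("convex_sphere", "torus", "concave_sphere")),
        round(p$center, 6), round(p$radius, 6)), numeric(5)))
    m[do.call(order, as.data.frame(m)), ]
  }
  ref <- quiet(build_ses(chain, surface_config(slab_count = 1L)))
  for (ns in 2:4) {
    got <- quiet(build_ses(chain, surface_config(slab_count = ns)))
    expect_equal(patch_census(got), patch_census(ref))
    expect_equal(sig(got), sig(ref), tolerance = 1e-6)
    ids <- vapply(got$patches, `[[`, integer(1), "id")
    expect_identical(ids, seq_along(got$patches))
  }
  # a single atom builds one patch regardless of the requested slab count
  one <- make_fixture("single_atom")$atoms
  for (ns in c(1L, 4L))
    expect_equal(length(quiet(build_ses(one,
      surface_config(slab_count = ns)))$patches), 1L)
})
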
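test_that("field fitting follows the three-sigma rule", {
  # axis-aligned box spanning 18 A in each direction -> sigma = 3 each
  pts <- as.matrix(expand.grid(x = c(-9, 9), y = c(-9, 9), z = c(-9, 9)))
  fld <- fit_field(pts)
  expect_equal(sort(fld$sigmas), c(3, 3, 3), tolerance = 1e-9)
  expect_equal(fld$center, c(0, 0, 0), tolerance = 1e-9,
               ignore_attr = TRUE)

  # collinear points spanning 30 A: long sigma 5, degenerate axes floored
  line <- cbind(seq(0, 30, length.out = 7), 0, 0)
  expect_warning(fld2 <- fit_field(line), "floored")
  expect_equal(sort(fld2$sigmas), c(1, 1, 5), tolerance = 1e-9)

  expect_error(fit_field(matrix(1, 1, 3)), "at least 2")
  expect_error(fit_field(matrix(2, 5, 3)), "coincide")
})

test_that("fitted rotation diagonalizes the cloud and centers its box", {
  set.seed(21)
  pts <- matrix(rnorm(150), 50, 3) %*% diag(c(6, 3, 1))
  pts <- rigid_transform(pts, angle = 1.1)
  fld <- fit_field(pts)
  rotated <- sweep(pts, 2, colMeans(pts)) %*% t(fld$rotation)
  cv <- stats::cov(rotated)
  expect_lt(max(abs(cv[upper.tri(cv)])), 1e-8)
  expect_true(all(diff(diag(cv)) <= 1e-8))   # descending variance order
  # recompute the center independently: bounding-box midpoint mapped back
  u <- sweep(pts, 2, fld$center) %*% t(fld$rotation)
  expect_equal(apply(u, 2, function(v) (min(v) + max(v)) / 2), c(0, 0, 0),
               tolerance = 1e-9)
  # rotation is orthonormal and right-handed
  expect_equal(fld$rotation %*% t(fld$rotation), diag(3), tolerance = 1e-8)
  expect_equal(det(fld$rotation), 1, tolerance = 1e-8)
})

test_that("theoretical profile matches direct per-residue evaluation", {
  # 5-residue toy evaluated against an independent scalar computation
  pos <- rbind(c(0, 0, 0), c(3, 1, -2), c(-4, 2, 1), c(6, -3, 2),
               c(-1, -5, -3))
  fld <- fit_field(pos)
  prof <- theoretical_profile(fld, pos)
  manual <- numeric(5)
  for (j in 1:5) {
    u <- fld$rotation %*% (pos[j, ] - fld$center)
    manual[j] <- exp(-u[1]^2 / (2 * fld$sigmas[1]^2)) *
      exp(-u[2]^2 / (2 * fld$sigmas[2]^2)) *
      exp(-u[3]^2 / (2 * fld$sigmas[3]^2))
  }
  expect_equal(as.numeric(prof), manual / sum(manual), tolerance = 1e-12)

  # residue at the field center carries the largest value
  pos2 <- rbind(fld$center, pos)
  expect_equal(which.max(theoretical_profile(fld, pos2)), 1L)

  # mirror-symmetric pair about the center splits 0.5 / 0.5
  pair <- rbind(c(2, 1, 0), c(-2, -1, 0))
  fld3 <- fit_field(rbind(pair, c(0, 0, 3), c(0, 0, -3),
                          c(1, -2, 1), c(-1, 2, -1)))
  expect_equal(as.numeric(theoretical_profile(fld3, pair)), c(0.5, 0.5),
               tolerance = 1e-9)
})

test_that("theoretical profile is invariant under rigid-body motion", {
  glob <- make_globule(n_residues = 80, seed = 13)
  pos <- as.matrix(glob$residues[, c("x", "y", "z")])
  p1 <- theoretical_profile(fit_field(pos), pos)
  moved <- rigid_transform(pos)
  p2 <- theoretical_profile(fit_field(moved), moved)
  expect_lt(max(abs(as.numeric(p1) - as.numeric(p2))), 1e-6)
})

test_that("observed profile matches the O(N^2) brute-force oracle", {
  set.seed(31)
  for (rep in 1:6) {
    n <- sample(10:40, 1)
    pos <- matrix(rnorm(3 * n, sd = 6), n, 3)
    h <- runif(n)
    expect_lt(max(abs(as.numeric(observed_profile(pos, h)) -
                      brute_observed(pos, h))), 1e-9)
  }
  # boundary: the interaction weight vanishes exactly at the cutoff
  expect_identical(interaction_weight(9, 9), 0)
  expect_equal(interaction_weight(0, 9), 1)
  # only self terms when all pairs exceed the cutoff
  pos <- rbind(c(0, 0, 0), c(20, 0, 0))
  expect_equal(as.numeric(observed_profile(pos, c(0.3, 0.3))), c(0.5, 0.5))
  expect_error(observed_profile(pos, c(1, 2, 3)), "mismatched")
  expect_error(observed_profile(pos, c(1, 1), cutoff = -1), "positive")
})

test_that("observed profile converges to intrinsic as the cutoff shrinks", {
  set.seed(41)
  pos <- matrix(rnorm(60, sd = 8), 20, 3)
  h <- runif(20, 0.1, 1)
  o_tiny <- observed_profile(pos, h, cutoff = 1e-6)
  expect_equal(as.numeric(o_tiny), as.numeric(intrinsic_profile(h)),
               tolerance = 1e-9)
})

test_that("intrinsic and uniform profiles normalize over their subset", {
  expect_equal(as.numeric(intrinsic_profile(rep("L", 4))), rep(0.25, 4))
  expect_equal(as.numeric(uniform_profile(4)), rep(0.25, 4))
  expect_equal(as.numeric(uniform_profile(1)), 1)
  # fragment renormalization: any subset sums to 1 on its own
  aa <- c("I", "R", "S", "W", "K", "F", "A", "D", "G", "Y")
  full <- intrinsic_profile(aa)
  frag <- intrinsic_profile(aa[3:7])
  expect_equal(sum(frag), 1, tolerance = 1e-12)
  s <- hydro_scale()
  expect_equal(as.numeric(frag), unname(s[aa[3:7]] / sum(s[aa[3:7]])),
               tolerance = 1e-12)
  # proportional to the packaged scale entries
  expect_equal(as.numeric(full), unname(s[aa] / sum(s[aa])),
               tolerance = 1e-12)
  expect_error(intrinsic_profile(c("R", "R")), "zero")
  expect_error(uniform_profile(0), ">= 1")
})

test_that("KL divergence matches direct summation and Gibbs' inequality", {
  expect_equal(kl_divergence(c(0.5, 0.5), c(0.5, 0.5)), 0)
  expect_equal(kl_divergence(c(1, 0), c(0.5, 0.5)), 1)  # 1 bit, closed form
  set.seed(51)
  for (rep in 1:10) {
    p <- runif(20); p <- p / sum(p)
    q <- runif(20); q <- q / sum(q)
    expect_equal(kl_divergence(p, q), brute_kl(p, q), tolerance = 1e-12)
    expect_gte(kl_divergence(p, q), 0)
  }
  expect_error(kl_divergence(c(1, 0), c(1, 0, 0)), "length")
})

test_that("relative distance spans [0,1] with the 0.5 threshold semantics", {
  expect_equal(relative_distance(0, 2), 0)
  expect_equal(relative_distance(1, 1), 0.5)
  expect_equal(relative_distance(1, 3), 0.25)
  expect_error(relative_distance(0, 0), "undefined")
  # strictly increasing in the O|T divergence at fixed reference
  rd <- vapply(seq(0.1, 3, by = 0.1), relative_distance, numeric(1),
               dkl_oref = 1.5)
  expect_true(all(diff(rd) > 0))
})

test_that("profile correlations reproduce the textbook formula", {
  t <- c(0.1, 0.2, 0.3, 0.4); o <- t
  expect_equal(unname(fod_correlations(rev(t), t, o)["tvo"]), 1)
  # affine decreasing relation gives exactly -1
  h <- c(0.4, 0.3, 0.2, 0.1); o2 <- 1 - 2 * h
  expect_equal(unname(fod_correlations(h, t, o2 / sum(o2))["hvo"]), -1)
  set.seed(61)
  h <- runif(30); t2 <- runif(30); o3 <- runif(30)
  cors <- fod_correlations(h, t2, o3)
  direct <- function(a, b) {
    mean((a - mean(a)) * (b - mean(b))) /
      (sqrt(mean((a - mean(a))^2)) * sqrt(mean((b - mean(b))^2)))
  }
  expect_equal(unname(cors["hvt"]), direct(h, t2), tolerance = 1e-12)
  expect_equal(unname(cors["tvo"]), direct(t2, o3), tolerance = 1e-12)
  expect_equal(unname(cors["hvo"]), direct(h, o3), tolerance = 1e-12)
  w <- capture_warnings(z <- fod_correlations(rep(0.25, 4), t, o))
  expect_match(w, "zero variance", all = TRUE)
  expect_true(is.na(z["hvt"]))
  expect_true(is.na(z["hvo"]))
  expect_false(is.na(z["tvo"]))
  expect_error(fod_correlations(1, 1, 1), "at least 3")
})

test_that("residue categories follow the O-vs-T comparison", {
  t <- c(0.4, 0.3, 0.2, 0.1)
  # O = T everywhere: only accordant labels, split by the T median
  cats <- classify_residues(t, t, tau = 0.01)
  expect_true(all(cats %in% c("core_accordant", "surface_accordant")))
  expect_equal(as.character(cats[1]), "core_accordant")
  expect_equal(as.character(cats[4]), "surface_accordant")
  # planted excess observed hydrophobicity -> exposed
  o <- t; o[4] <- o[4] + 0.3; o <- o / sum(o)
  expect_equal(as.character(classify_residues(t, o, tau = 0.02)[4]),
               "hydrophobic_exposed")
  # deficit -> internalized hydrophilic
  o2 <- t; o2[1] <- 0.05; o2 <- o2 / sum(o2)
  expect_equal(as.character(classify_residues(t, o2, tau = 0.02)[1]),
               "hydrophilic_internalized")
  # labels are stable under residue reordering
  fib <- make_fibril(n_chains = 4, chain_length = 12, seed = 8)
  r <- analyze_unit(fib, selection_spec("protofibril"))
  set.seed(71)
  perm <- sample(nrow(r$profiles))
  cats_perm <- classify_residues(r$profiles$T[perm], r$profiles$O[perm])
  expect_equal(as.character(cats_perm), as.character(r$profiles$category[perm]))
})

test_that("discordant-residue elimination removes the planted outlier first", {
  toy <- outlier_toy()
  e <- eliminate_discordant(toy$t, toy$o, toy$r)
  expect_equal(e$removed[1], as.character(toy$outlier))
  expect_lt(e$final_rd, 0.5)
  expect_false(e$irreducible)
  expect_true(all(diff(e$rd_trace) <= 1e-12))

  # structure already accordant: nothing removed
  t <- c(0.4, 0.3, 0.2, 0.1)
  e0 <- eliminate_discordant(t, t, rep(0.25, 4))
  expect_equal(length(e0$removed), 0L)

  # each step removes the residue with the largest renormalized |O - T| gap,
  # verified against an explicit per-step search over survivors
  fib <- make_fibril(n_chains = 4, chain_length = 12, seed = 2)
  r <- analyze_unit(fib, selection_spec("protofibril"))
  t2 <- r$profiles$T; o2 <- r$profiles$O; r2 <- r$profiles$R
  e2 <- eliminate_discordant(t2, o2, r2, keys = as.character(seq_along(t2)))
  alive <- rep(TRUE, length(t2))
  for (k in seq_along(e2$removed)) {
    idx <- which(alive)
    gap <- abs(o2[idx] / sum(o2[idx]) - t2[idx] / sum(t2[idx]))
    expect_equal(e2$removed[k], as.character(idx[which.max(gap)]))
    alive[idx[which.max(gap)]] <- FALSE
  }
})

test_that("elimination ties break toward the lower residue index", {
  # symmetric peaked T with two exactly tied end outliers in O
  n <- 8
  t <- exp(-((1:n - (n + 1) / 2)^2) / 6); t <- t / sum(t)
  o <- c(0.3, rep(0.05, 6), 0.3); o <- o / sum(o)
  expect_identical(abs(o - t)[1], abs(o - t)[n])  # exact tie by symmetry
  e <- eliminate_discordant(t, o, rep(1 / n, n))
  expect_equal(e$removed[1:2], c("1", "8"))
})

test_that("core residues require jointly high T and O", {
  t <- c(0.4, 0.3, 0.2, 0.1); o <- c(0.35, 0.15, 0.3, 0.2)
  keys <- letters[1:4]
  expect_equal(core_residues(t, o, q = 0.75, keys = keys), "a")
  # degenerate quantile on uniform profiles includes everyone (>= convention)
  expect_equal(core_residues(rep(0.25, 4), rep(0.25, 4), keys = keys), keys)
  # the jointly maximal residue survives any quantile
  for (q in c(0.1, 0.5, 0.9))
    expect_true("a" %in% core_residues(t, o, q = q, keys = keys))
  # synthetic globule: the core concentrates in the generator's inner-half
  # region where it planted the hydrophobic residue types
  glob <- make_globule(seed = 17)
  r <- analyze_unit(glob, selection_spec("chain_alone"))
  core <- core_residues(r$profiles$T, r$profiles$O,
                        keys = seq_len(nrow(r$profiles)))
  pos <- as.matrix(glob$residues[core, c("x", "y", "z")])
  d <- sqrt(rowSums(sweep(pos, 2, r$field$center)^2))
  radius <- 3.2 * 200^(1 / 3)          # generator default for n = 200
  expect_lt(stats::median(d), radius / 2)
})

test_that("2D field suppresses the long axis and is cross-section invariant", {
  fib <- make_fibril(n_chains = 12, seed = 7)
  pos <- as.matrix(fib$residues[, c("x", "y", "z")])
  fld <- fit_field(pos, "gauss2d")
  # the suppressed axis is the stacking (largest-span) direction
  spans <- apply(sweep(pos, 2, colMeans(pos)) %*% t(fld$rotation), 2,
                 function(u) diff(range(u)))
  expect_equal(fld$suppressed_axis, which.max(spans))
  ax <- fld$rotation[fld$suppressed_axis, ]
  expect_gt(abs(ax[3]), 0.99)  # stacking is along z by construction

  # adding one repeat unit leaves per-cross-section profiles unchanged
  pp <- function(f) {
    p <- as.matrix(f$residues[, c("x", "y", "z")])
    cross_section_profiles(fit_field(p, "gauss2d"), p, f$residues$chain)
  }
  f5 <- make_fibril(n_chains = 5, chain_length = 8, seed = 7)
  f6 <- make_fibril(n_chains = 6, chain_length = 8, seed = 7)
  expect_lt(max(abs(pp(f5)[["A"]] - pp(f6)[["A"]])), 1e-6)
  expect_lt(max(abs(pp(f5)[["C"]] - pp(f6)[["E"]])), 1e-6)
  expect_error(cross_section_profiles(fit_field(pos), pos,
                                      fib$residues$chain), "gauss2d")
})
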
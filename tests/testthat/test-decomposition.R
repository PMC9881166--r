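test_that("decomposition handles identity, pure translation and references", {
  fr <- toy_frame()
  id <- rad_decompose(rad_transform(diag(3)), fr)
  expect_equal(id$phi, 0, tolerance = 1e-9)
  expect_equal(id$theta, 0, tolerance = 1e-9)
  expect_false(id$psi_defined)
  expect_equal(id$delta_x_norm, 0, tolerance = 1e-9)

  tr <- rad_transform(diag(3), c(1, -2, 3))
  pt <- rad_decompose(tr, fr)
  expect_equal(pt$phi, 0, tolerance = 1e-9)
  expect_equal(pt$theta, 0, tolerance = 1e-9)
  expect_equal(pt$delta_x, c(1, -2, 3), tolerance = 1e-9)
})

test_that("a constructed (phi, theta, psi) transform decomposes exactly", {
  fr <- toy_frame()
  tr <- frame_affine(fr, 7, 3, 40)
  ang <- rad_decompose(tr, fr)
  expect_equal(ang$phi, 7, tolerance = 1e-6)
  expect_equal(ang$theta, 3, tolerance = 1e-6)
  expect_equal(ang$psi, 40, tolerance = 1e-6)
  expect_equal(ang$delta_x_norm, 0, tolerance = 1e-9)
  # brute-force check: rebuild the matrix from the outputs
  expect_lt(max(abs(reconstruct_rotation(fr, ang$phi, ang$theta, ang$psi) -
                      tr$R)), 1e-9)
  # rotated axis is the image of the reference axis
  expect_equal(ang$rotated_axis, as.numeric(tr$R %*% fr$axis_direction),
               tolerance = 1e-12)
})

test_that("decompose-reconstruct round-trips over random angle triples", {
  set.seed(201)
  fr <- toy_frame()
  for (i in 1:50) {
    phi <- runif(1, -20, 25)
    theta <- runif(1, 0.3, 15)
    psi <- runif(1, -179.999, 180)
    ang <- rad_decompose(frame_affine(fr, phi, theta, psi), fr)
    expect_equal(ang$phi, phi, tolerance = 1e-6)
    expect_equal(ang$theta, theta, tolerance = 1e-6)
    expect_equal(ang$psi, psi, tolerance = 1e-6)
    expect_lt(max(abs(reconstruct_rotation(fr, ang$phi, ang$theta, ang$psi) -
                        frame_affine(fr, phi, theta, psi)$R)), 1e-9)
  }
})

test_that("residual translation is minimal over the axis and anchor-invariant", {
  set.seed(202)
  fr <- toy_frame()
  tr <- frame_affine(fr, 9, 4, -60, dx = c(1.5, -0.7, 0.9))
  ang <- rad_decompose(tr, fr)
  # |dx| at x_c is minimal among points along the reference axis
  resid_at <- function(s) {
    x <- fr$axis_point + s * fr$axis_direction
    sqrt(sum((as.numeric((tr$R - diag(3)) %*% x) + tr$t)^2))
  }
  ss <- seq(-100, 100, length.out = 401)
  expect_lte(ang$delta_x_norm, min(vapply(ss, resid_at, numeric(1))) + 1e-9)

  # shifting the stored anchor along the axis changes nothing
  fr2 <- fr
  fr2$axis_point <- fr$axis_point + 37.5 * fr$axis_direction
  ang2 <- rad_decompose(tr, fr2)
  expect_equal(ang2$delta_x_norm, ang$delta_x_norm, tolerance = 1e-9)
  expect_equal(ang2$x_c, ang$x_c, tolerance = 1e-6)
  expect_equal(ang2$phi, ang$phi, tolerance = 1e-9)
})

test_that("er_angle is a metric-like rotation distance with additivity", {
  set.seed(203)
  R1 <- random_rotation()
  expect_equal(er_angle(R1, R1), 0, tolerance = 1e-9)

  # same-axis rotations: 5 and 8 degrees differ by 3
  ax <- c(0.3, -0.5, 0.81)
  expect_equal(er_angle(rot_axis_angle(ax, 5), rot_axis_angle(ax, 8)), 3,
               tolerance = 1e-9)

  for (i in 1:100) {
    Ra <- random_rotation(); Rb <- random_rotation()
    expect_lt(abs(er_angle(Ra, Rb) - quat_distance(Ra, Rb)), 1e-9)
    expect_equal(er_angle(Ra, Rb), er_angle(Rb, Ra), tolerance = 1e-12)
  }
})

test_that("theta = 0 makes er_angle against the reference equal |phi|", {
  fr <- toy_frame()
  for (phi in c(-12.5, -2, 0.5, 7, 19)) {
    tr <- frame_affine(fr, phi, 0, 0)
    expect_equal(er_angle(tr, diag(3)), abs(phi), tolerance = 1e-9)
    ang <- rad_decompose(tr, fr)
    expect_equal(ang$phi, phi, tolerance = 1e-9)
    expect_false(ang$psi_defined)
  }
})

test_that("delta_theta measures tilt difference independent of rotation", {
  fr <- toy_frame()
  # both untilted, different phi: delta_theta = 0
  a <- frame_affine(fr, 3, 0, 0)
  b <- frame_affine(fr, 11, 0, 0)
  expect_equal(delta_theta(a, b, fr), 0, tolerance = 1e-9)

  # same tilt direction: difference of tilt values
  a <- frame_affine(fr, 2, 2, 55)
  b <- frame_affine(fr, 9, 5, 55)
  expect_equal(delta_theta(a, b, fr), 3, tolerance = 1e-9)

  # opposite tilt directions, both 3 degrees: 6 degrees apart
  a <- frame_affine(fr, 0, 3, 20)
  b <- frame_affine(fr, 0, 3, -160)
  expect_equal(delta_theta(a, b, fr), 6, tolerance = 1e-9)

  # invariant when either argument is composed with a rotation about its
  # own current axis
  set.seed(204)
  a <- frame_affine(fr, 5, 4, 80)
  b <- frame_affine(fr, -3, 2, -40)
  base <- delta_theta(a, b, fr)
  axis_a <- as.numeric(a$R %*% fr$axis_direction)
  spin <- rad_transform(rot_axis_angle(axis_a, 37))
  a2 <- rad_transform(spin$R %*% a$R)
  expect_equal(delta_theta(a2, b, fr), base, tolerance = 1e-9)
})

test_that("nearest neighbors match sequential gaps and a brute-force oracle", {
  # phi gaps: 0, 1, 5 -> gaps 1 and 4
  nn <- nearest_neighbors(c(s1 = 0, s2 = 1, s3 = 5), metric = "phi_gap")
  expect_equal(nn$gap, c(1, 4))
  expect_equal(nn$accession, c("s1", "s2"))

  # duplicate orientations -> distance 0
  R <- rot_axis_angle(c(0, 0, 1), 5)
  nn2 <- nearest_neighbors(list(a = R, b = R, c = rot_axis_angle(c(0, 0, 1), 9)),
                           metric = "er_angle")
  expect_equal(nn2$distance[nn2$accession == "a"], 0, tolerance = 1e-9)

  # E-R nearest of the 5-degree structure is the 1-degree structure
  ens <- list(x0 = rot_axis_angle(c(1, 0, 0), 0),
              x1 = rot_axis_angle(c(1, 0, 0), 1),
              x5 = rot_axis_angle(c(1, 0, 0), 5))
  nn3 <- nearest_neighbors(ens, metric = "er_angle")
  expect_equal(nn3$neighbor[nn3$accession == "x5"], "x1")
  expect_equal(nn3$distance[nn3$accession == "x5"], 4, tolerance = 1e-9)

  # random ensemble against an independent quaternion all-pairs oracle
  set.seed(205)
  ens <- lapply(1:25, function(i) random_rotation())
  names(ens) <- paste0("r", 1:25)
  nn4 <- nearest_neighbors(ens, metric = "er_angle")
  for (i in seq_along(ens)) {
    d <- vapply(seq_along(ens), function(j)
      if (i == j) Inf else quat_distance(ens[[i]], ens[[j]]), numeric(1))
    expect_equal(nn4$neighbor[i], names(ens)[which.min(d)])
    expect_equal(nn4$distance[i], min(d), tolerance = 1e-9)
  }
})

test_that("net_domain_transform recovers applied domain transforms", {
  fxf <- shared_fixture()
  fx <- fxf$fx

  # the classical reference against itself: identity
  nt <- net_domain_transform(fx$classical, fx$reference, "body")
  expect_lt(er_angle(nt$transform, diag(3)), 1e-6)
  expect_lt(sqrt(sum(nt$transform$t^2)), 1e-6)

  # a noiseless model with a known compound transform
  spec <- tiny_spec(seed = 77,
                    body_truth = list(phi = 6, theta = 2.5, psi = 110,
                                      dx = c(0.8, 0.1, -0.4)),
                    head_truth = list(phi = -4, theta = 6, psi = -75,
                                      dx = c(0, 0.5, 0)))
  m <- generate_model(spec, fx, fxf$frames)
  for (d in c("body", "head")) {
    nt <- net_domain_transform(m$structure, fx$reference, d)
    ang <- rad_decompose(nt$transform, fxf$frames[[d]])
    tr <- m$truth[[d]]
    expect_equal(ang$phi, tr$phi, tolerance = 1e-6)
    expect_equal(ang$theta, tr$theta, tolerance = 1e-6)
    expect_equal(ang$psi, tr$psi, tolerance = 1e-5)
    expect_equal(ang$delta_x_norm, tr$delta_x_norm, tolerance = 1e-6)
  }
})

test_that("isolated SSUs support head analysis only", {
  fxf <- shared_fixture()
  fx <- fxf$fx
  atoms <- fx$classical$atoms
  iso <- rad_structure(atoms[atoms$chain == "B", 1:10], accession = "ISO-SSU",
                       lsu_chain = NULL, ssu_chain = "B")
  expect_error(net_domain_transform(iso, fx$reference, "body"), "LSU")
  res <- analyze_structure(iso, fx$reference, fxf$frames)
  expect_equal(res$table$domain, "head")
  expect_equal(res$head$angles$phi, 0, tolerance = 1e-6)
})

test_that("analyze_structure produces a complete orientation table", {
  fxf <- shared_fixture()
  spec <- tiny_spec(seed = 78,
                    body_truth = list(phi = 8, theta = 3, psi = 40,
                                      dx = c(0, 0, 0)),
                    head_truth = list(phi = 18, theta = 5, psi = -30,
                                      dx = c(1, 0, 0)))
  m <- generate_model(spec, fxf$fx, fxf$frames)
  res <- analyze_structure(m$structure, fxf$fx$reference, fxf$frames)
  expect_equal(res$table$domain, c("body", "head"))
  expect_equal(res$table$phi, c(8, 18), tolerance = 1e-5)
  expect_equal(res$table$theta, c(3, 5), tolerance = 1e-5)
  expect_true(all(res$table$core_rmsd < 1e-6))
  f <- tempfile(fileext = ".tsv")
  write_orientation_table(res$table, f)
  expect_equal(read_orientation_table(f)$phi, res$table$phi,
               tolerance = 1e-12)
})
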
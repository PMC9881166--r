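# small structure with two protein chains (CA atoms) and two rRNA chains,
# with probe sites at controlled positions
probe_structure <- function(d_offset = c(3, 4, 0)) {
  prot <- function(chain, n, resno, origin) {
    data.frame(elety = "CA", elesy = "C",
               resid = rep(c("ALA", "GLY", "SER", "LEU"), length.out = n),
               chain = chain, resno = resno, insert = "",
               x = origin[1] + seq_len(n) * 3.8, y = origin[2],
               z = origin[3], o = 1, stringsAsFactors = FALSE)
  }
  rna <- function(chain, n, origin) {
    data.frame(elety = "P", elesy = "P",
               resid = sample(c("A", "C", "G", "U"), n, TRUE), chain = chain,
               resno = seq_len(n), insert = "",
               x = origin[1] + seq_len(n) * 5.9, y = origin[2], z = origin[3],
               o = 1, stringsAsFactors = FALSE)
  }
  atoms <- rbind(prot("S", 60, 1:60, c(0, 0, 0)),
                 prot("L", 30, 1:30, c(0, 50, 0)),
                 rna("R", 600, c(0, 100, 0)), rna("Q", 560, c(0, 150, 0)))
  # place S residue 41 CA and L residue 11 CA at a known separation
  atoms[atoms$chain == "S" & atoms$resno == 41, c("x", "y", "z")] <- c(0, 0, 0)
  atoms[atoms$chain == "L" & atoms$resno == 11, c("x", "y", "z")] <- d_offset
  rad_structure(atoms, accession = "PROBE", lsu_chain = "R", ssu_chain = "Q")
}

test_that("probe distances follow the Euclidean and centroid rules", {
  set.seed(301)
  st <- probe_structure(c(3, 4, 0))
  spec <- probe_spec("AB", probe_site("S6", 41, "CA"),
                     probe_site("L9", 11, "CA"))
  cm <- list(S6 = "S", L9 = "L")
  expect_equal(probe_distance(st, spec, chain_map = cm), 5)

  # geometric center over identical coordinates is that coordinate
  st2 <- st
  rows <- st2$atoms$chain == "Q" & st2$atoms$resno %in% 10:13
  st2$atoms[rows, c("x", "y", "z")] <-
    matrix(c(7, 8, 9), 4, 3, byrow = TRUE)
  cspec <- probe_spec("CC", probe_site("16S", 10:13, "center"),
                      probe_site("S6", 41, "CA"))
  expect_equal(probe_distance(st2, cspec, chain_map = cm),
               sqrt(sum(c(7, 8, 9)^2)))

  # known separation round-trips
  st3 <- probe_structure(c(47, 0, 0))
  expect_equal(probe_distance(st3, spec, chain_map = cm), 47)
})

test_that("probe distance is invariant under global rigid transforms", {
  set.seed(302)
  st <- probe_structure(c(12, -5, 31))
  spec <- builtin_probe_specs()$S6_L9
  cm <- list(S6 = "S", L9 = "L")
  d0 <- probe_distance(st, spec, chain_map = cm)
  G <- rad_transform(rot_axis_angle(rnorm(3), 117), c(40, -12, 7))
  expect_equal(probe_distance(transform_structure(st, G), spec,
                              chain_map = cm), d0, tolerance = 1e-9)
})

test_that("unresolvable sites yield NA with a report, not an error", {
  set.seed(303)
  st <- probe_structure()
  spec <- probe_spec("XY", probe_site("S6", 999, "CA"),
                     probe_site("L9", 11, "CA"))
  d <- probe_distance(st, spec, chain_map = list(S6 = "S", L9 = "L"))
  expect_true(is.na(d))
  expect_match(attr(d, "report"), "unresolvable")
  # unknown molecule label with no chain map
  d2 <- probe_distance(st, builtin_probe_specs()$S6_L9)
  expect_true(is.na(d2))
})

test_that("protein chains are identified by sequence when references given", {
  set.seed(304)
  st <- probe_structure()
  tab <- chain_residue_table(st, "S")
  aa1 <- c(ALA = "A", GLY = "G", SER = "S", LEU = "L")
  sref <- paste(aa1[tab$resid], collapse = "")
  spec <- probe_spec("AB", probe_site("S6", 41, "CA"),
                     probe_site("L9", 11, "CA"))
  d <- probe_distance(st, spec, chain_map = list(L9 = "L"),
                      ref_seqs = list(S6 = sref))
  expect_equal(d, 5)
  # a wrong reference sequence below the identity floor fails to resolve
  d2 <- probe_distance(st, spec, chain_map = list(L9 = "L"),
                       ref_seqs = list(S6 = strrep("W", 60)))
  expect_true(is.na(d2))
})

test_that("tanh response fits recover generating parameters", {
  set.seed(305)
  x <- seq(-2, 14, length.out = 60)
  y0 <- 50 + 5 * tanh((x - 5.5) / 1.5)

  # exact data: near-zero residuals and exact parameters
  fit0 <- fit_sigmoid(x, y0)
  expect_true(fit0$converged)
  expect_lt(max(abs(fit0$residuals)), 1e-8)
  expect_equal(fit0$midpoint, 5.5, tolerance = 1e-6)

  # noisy data: parameters within 10%
  y <- y0 + rnorm(length(x), sd = 0.2)
  fit <- fit_sigmoid(x, y)
  expect_true(fit$converged)
  expect_equal(fit$baseline, 50, tolerance = 0.1)
  expect_equal(fit$amplitude, 5, tolerance = 0.5)
  expect_equal(fit$midpoint, 5.5, tolerance = 0.55)
  expect_equal(fit$width, 1.5, tolerance = 0.15)
  expect_equal(fit$responsive_range, c(fit$midpoint - fit$width,
                                       fit$midpoint + fit$width))

  # constant response: amplitude ~ 0, midpoint unidentifiable
  flat <- fit_sigmoid(x, rep(50, length(x)))
  expect_false(flat$converged)
  expect_equal(flat$amplitude, 0)
  expect_true(is.na(flat$midpoint))

  expect_error(fit_sigmoid(1:4, 1:4), "5 points")
  expect_error(fit_sigmoid(rep(1, 10) + rnorm(10, sd = 0.01), rnorm(10)),
               "spanning")
})

test_that("power-law response fits recover generating parameters", {
  set.seed(306)
  x <- seq(0, 15, length.out = 50)
  y0 <- 44 + 1.8 * (x - min(x) + 1)^0.7

  fit0 <- fit_powerlaw(x, y0)
  expect_true(fit0$converged)
  expect_lt(max(abs(fit0$residuals)), 1e-6)
  expect_equal(fit0$exponent, 0.7, tolerance = 1e-4)
  expect_equal(fit0$scale, 1.8, tolerance = 1e-3)

  y <- y0 + rnorm(length(x), sd = 0.2)
  fit <- fit_powerlaw(x, y)
  expect_true(fit$converged)
  expect_equal(fit$exponent, 0.7, tolerance = 0.15)

  # fitted curve is monotone over the data range for monotone data
  xs <- x - min(x) + 1
  curve <- fit$offset + fit$scale * xs^fit$exponent
  expect_true(all(diff(curve) > 0))

  flat <- fit_powerlaw(x, rep(44, length(x)))
  expect_false(flat$converged)
  expect_equal(flat$exponent, 0)
})

test_that("correlation analysis reports Pearson/Spearman with filtering", {
  set.seed(307)
  phi <- seq(-2, 14, length.out = 40)
  rec <- data.frame(accession = paste0("S", 1:40), phi_body = phi,
                    R_S6_L9 = 50 + 0.8 * phi, resolution = 3)
  out <- correlate_distances(rec, "R_S6_L9", "phi_body")
  expect_equal(out$pearson, 1, tolerance = 1e-12)
  expect_equal(out$spearman, 1, tolerance = 1e-12)
  expect_equal(out$n, 40)

  rec$R_S6_L9 <- 60 - 0.8 * phi
  expect_equal(correlate_distances(rec, "R_S6_L9", "phi_body")$pearson, -1,
               tolerance = 1e-12)

  # permuted pairs: correlation collapses toward zero
  rec$R_S6_L9 <- sample(50 + 0.8 * phi)
  expect_lt(abs(correlate_distances(rec, "R_S6_L9", "phi_body")$pearson),
            0.45)

  # resolution filter drops low-resolution entries
  rec$resolution[1:30] <- 8
  expect_equal(correlate_distances(rec, "R_S6_L9", "phi_body")$n, 10)
})
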
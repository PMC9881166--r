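# Shared synthetic fixtures, built once per test run.

# small reference fixture + frames used across module tests
.shared <- new.env(parent = emptyenv())

tiny_spec <- function(seed = 11, ...) {
  fixture_spec(seed = seed, n_lsu = 600, n_body = 400, n_head = 160, ...)
}

shared_fixture <- function() {
  if (is.null(.shared$fx)) {
    .shared$fx <- generate_reference_fixture(tiny_spec())
    .shared$frames <- fixture_frames(.shared$fx)
  }
  list(fx = .shared$fx, frames = .shared$frames)
}

# a frame detached from any structure, for pure-geometry tests
toy_frame <- function(axis = c(0.25, 0.1, 0.96), point = c(85, 0, -5),
                      zero = c(0, 1, 0.2)) {
  a <- axis / sqrt(sum(axis^2))
  z <- zero - sum(zero * a) * a
  structure(list(domain = "body", axis_direction = a, axis_point = point,
                 zero_tilt_direction = z / sqrt(sum(z^2)),
                 frame_of = "LSU_core", reference_angle = 8,
                 provenance = list()), class = "rad_frame")
}

# affine transform realizing (phi, theta, psi) about a frame, with residual
# translation dx added at the frame's axis point (dx not canonicalized)
frame_affine <- function(frame, phi, theta, psi, dx = c(0, 0, 0)) {
  R <- reconstruct_rotation(frame, phi, theta, psi)
  p <- frame$axis_point
  rad_transform(R, p - as.numeric(R %*% p) + dx)
}

# minimal one-P-per-residue structure with given chain lengths
chain_structure <- function(lengths, bases = NULL, accession = "TEST") {
  atoms <- do.call(rbind, lapply(seq_along(lengths), function(i) {
    n <- lengths[i]
    data.frame(elety = "P", elesy = "P",
               resid = if (is.null(bases)) sample(c("A", "C", "G", "U"), n,
                                                  TRUE) else bases[[i]],
               chain = LETTERS[i], resno = seq_len(n), insert = "",
               x = seq_len(n) * 5.9, y = i * 50, z = 0, o = 1,
               stringsAsFactors = FALSE)
  }))
  rad_structure(atoms, accession = accession)
}
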
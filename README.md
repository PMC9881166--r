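# radkit

Quantitative comparison of ribosome structures requires a common coordinate
system for the large-scale motions of the small subunit (SSU): the
ratchet-like rotation of the SSU body relative to the large subunit (LSU),
the swivel of the SSU head relative to the body, and the tilt-like
rearrangements ("rolling") superimposed on both. `radkit` describes the
orientation of each domain (body or head) by a complete rigid-body
decomposition:

- **φ** — primary rotation about a fixed reference axis **R̂**_ref (degrees);
- **θ** — tilt, the angle between the domain's current rotation axis
  **R̂** = R·**R̂**_ref and **R̂**_ref;
- **ψ** — tilt direction, the azimuth of the tilt axis (line of nodes)
  **T̂** ∝ **R̂**_ref × **R̂** measured from a fixed zero direction in the
  plane perpendicular to **R̂**_ref;
- **x**_c — the point on the reference axis minimizing the residual
  translation, and **Δx** — that minimal residual (Å).

The rotation convention is `R = Rot(T̂, θ) · Rot(R̂_ref, φ)`: tilting
re-orients the body-fixed rotation axis after the primary rotation. Reference
axes are built from a classical (unrotated) structure plus body-rotated and
head-rotated companions: superpose the two structures on the frame-of-
reference core (LSU rRNA core for the body, SSU-body rRNA core for the head)
and take the screw axis of the rigid transform relating the domain cores.
Pairwise metrics complete the toolkit: the Euler–Rodrigues angle
`φ^E–R = arccos((trace(Ra Rbᵀ) − 1)/2)` as a 1-D distance between any two
orientations, and the tilt difference `δθ = arccos((Ra·R̂_ref)·(Rb·R̂_ref))`,
which is independent of the primary rotation.

Domain cores are identified by global (Needleman–Wunsch) sequence alignment
of each rRNA chain to the reference, a head/body partition by a packaged
residue set in reference numbering, and iterative spatial pruning of the
matched phosphate (P) atoms to an RMSD target of ~1 Å. An smFRET module
computes published probe-pair distances (S6–L9, S11–L9, h44–H101) and fits
their response to rotation (tanh sigmoid and power-law forms). A seeded
synthetic pseudo-ribosome generator provides fixtures with exactly known
(φ, θ, ψ, Δx) so the entire pipeline is testable without downloading any
structures.

## Worked example

```r
library(radkit)

# synthetic reference triple and its frames
fx <- generate_reference_fixture(fixture_spec(seed = 1))
frames <- fixture_frames(fx)
frames$body
#> rad_frame (body): axis [0.2507, 0.1003, 0.9628] through [105.94, -5.72, 1.19];
#>   reference rotation 8.000 deg

# a model with known body and head motions, realistic noise and gaps
spec <- fixture_spec(seed = 42, noise_sigma = 0.3, dropout = 0.05,
                     body_truth = list(phi = 8, theta = 3, psi = 40, dx = c(0.5, 0, 0)),
                     head_truth = list(phi = 18, theta = 5, psi = -30, dx = c(1, 0, 0)))
m <- generate_model(spec, fx, frames)
analyze_structure(m$structure, fx$reference, frames)
#> rad_result: SYNMODEL-42
#>     accession domain    phi theta    psi dx_norm n_core core_rmsd frame_core_rmsd
#> 1 SYNMODEL-42   body  8.009 3.021  41.01  0.2829    730    0.5331          0.5069
#> 2 SYNMODEL-42   head 18.065 5.050 -30.50  0.9685    334    0.5076          0.5331
```

The body was generated with an 8° ratchet rotation, a 3° tilt in direction
40° and a 0.5 Å residual translation; with 0.3 Å coordinate noise and 5%
missing residues the pipeline recovers 8.009°, 3.021°, 41.0° — the applied
state to within the noise floor. `n_core` and `core_rmsd` report how many
matched P atoms survived pruning and their superposition RMSD.

Real structures go through the same interface: `read_structure()` on an
mmCIF/PDB file, `make_reference()` on a classical reference structure (with
the packaged 16S head definition and zero-tilt anchors), `build_body_frame()`
/ `build_head_frame()` on the rotated companions, then `analyze_structure()`.
A thin command-line wrapper is installed at `inst/cli/radkit`
(subcommands `fixtures`, `analyze`, `compare`, `summarize`).

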
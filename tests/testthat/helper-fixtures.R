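# Fixtures are built in code: simple tubes, tapers and raised-cosine lesion
# vessels with known closed-form profiles.

make_tube <- function(r = 2, L = 50, ds = 0.25, label = "tube") {
  s <- seq(0, L, by = ds)
  vessel_geometry(s, rep(r, length(s)), label = label)
}

make_taper <- function(r0 = 2.5, r1 = 1.5, L = 100, ds = 0.25, label = "taper") {
  s <- seq(0, L, by = ds)
  vessel_geometry(s, r0 + (r1 - r0) * s / L, label = label)
}

# raised-cosine dip(s): fraction of local baseline removed at s
cosine_dip <- function(s, a, b, depth) {
  ifelse(s > a & s < b, depth * 0.5 * (1 - cos(2 * pi * (s - a) / (b - a))), 0)
}

# tube or taper with one or more planted cosine lesions
# lesions: data.frame(a, b, depth)
make_lesion_vessel <- function(lesions, r0 = 2, r1 = r0, L = 60, ds = 0.25,
                               label = "lesioned") {
  s <- seq(0, L, by = ds)
  base <- r0 + (r1 - r0) * s / L
  shrink <- rep(1, length(s))
  for (i in seq_len(nrow(lesions))) {
    shrink <- shrink * (1 - cosine_dip(s, lesions$a[i], lesions$b[i],
                                       lesions$depth[i]))
  }
  vessel_geometry(s, base * shrink, label = label)
}

lesion_extents <- function(lesions) {
  tibble::tibble(start_mm = lesions$a, end_mm = lesions$b,
                 r_min_mm = NA_real_, r_ref_mm = NA_real_, pct_ds = NA_real_)
}

test_bc <- function(r_micro = 20, pa = 90, pv = 0) {
  boundary_condition(pa = pa, pv = pv, r_micro = r_micro)
}

test_fluid <- function() fluid_properties()

# analytic Poiseuille resistance of a uniform tube, mmHg s / mL
tube_rv <- function(r_mm, L_mm, mu = 0.0035) {
  8 * mu * (L_mm * 1e-3) / (pi * (r_mm * 1e-3)^4) / 133.322 / 1e6
}
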
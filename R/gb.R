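# Generalized Born implicit solvent (pairwise-descreening variant).
# Effective Born radii are computed with the Hawkins-Cramer-Truhlar
# descreening integral from the per-type intrinsic radii and screening
# factors in the parameter files; the polarization energy uses the
# canonical smoothed pairwise form. Dielectrics default to 1 (solute) and
# 78.5 (solvent). The analytic gradient includes the full chain rule
# through the coordinate dependence of the Born radii. The O(n^2) loop
# runs in the compiled kernel (src/kernels.cpp).

GB_OFFSET <- 0.09   # A, radius offset of the descreening integral
GB_RMAX <- 30.0     # A, cap on effective radii in pathological overlaps

gb_energy <- function(topology, X, config = default_config()) {
  fac <- -0.5 * COULOMB_KE *
    (1 / config$epsilon_in - 1 / config$epsilon_out)
  rho <- topology$gb_radius - GB_OFFSET
  out <- .gb_kernel(X, topology$pair_i, topology$pair_j, rho,
                    topology$gb_screen, topology$charges, fac, GB_RMAX)
  list(energy = out$energy, gradient = out$gradient)
}
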
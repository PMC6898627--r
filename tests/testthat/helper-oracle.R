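# Independent oracles. Both are written directly from the model
# equations, without calling any mucosim kinetics or integrator code, so
# they stay independent of the paths they check.

# Closed-form solution of the linear system for a pre-dissolved,
# well-stirred donor. With a = P*S/Vd (donor loss), c = P*S/Vr (back-flux
# from the receiver) and b = Q/Vr (washout),
#   Md' = -a Md + c Mr
#   Mr' =  a Md - (b + c) Mr
# which is solved exactly by eigendecomposition of the 2x2 rate matrix.
closed_form_solution_run <- function(t, M0, Pexp, hexp, hm, S, Vd, Vr, Q) {
  a <- (Pexp * hexp / hm) * S / Vd
  cc <- (Pexp * hexp / hm) * S / Vr
  b <- Q / Vr
  A <- matrix(c(-a, a, cc, -(b + cc)), nrow = 2)
  e <- eigen(A)
  w <- solve(e$vectors, c(M0, 0))
  sol <- sapply(t, function(tt)
    e$vectors %*% (w * exp(e$values * tt)))
  list(donor = sol[1, ], receiver = sol[2, ],
       collected = M0 - sol[1, ] - sol[2, ])
}

# Brute-force forward-Euler integration of the four-stock model with the
# kinetic laws written out inline.
naive_euler_oracle <- function(drug, apparatus, run, dt, t_end) {
  M0 <- run$dose
  Cs <- drug$solubility
  k <- drug$intrinsic_dissolution_rate / Cs
  d0 <- drug$particle_diameter
  rho <- drug$particle_density
  S <- apparatus$membrane_area
  Vd <- apparatus$mucus_volume
  Vr <- apparatus$receiver_volume
  Q <- apparatus$perfusate_flow
  ht <- Vd / S
  hm <- apparatus$membrane_thickness
  particles <- run$dose_form == "particles"
  well <- run$stirring == "well_stirred"
  solid <- if (particles) M0 else 0
  dissolved <- if (particles) 0 else M0
  receiver <- 0
  collected <- 0
  n <- round(t_end / dt)
  for (i in seq_len(n)) {
    conc <- dissolved / Vd
    concp <- receiver / Vr
    if (particles && solid > 0) {
      dt_diam <- (solid * d0^3 / M0)^(1 / 3)
      area <- 6 * M0 * dt_diam^2 / (d0^3 * rho)
      diss <- max(0, k * area * (Cs - conc))
    } else diss <- 0
    fd <- (receiver + collected) / M0
    p <- if (well) drug$permeability_exp * drug$membrane_thickness_exp / hm
         else drug$permeability_exp * drug$membrane_thickness_exp /
              (hm + fd * ht)
    perm <- p * S * (conc - concp)
    coll <- concp * Q
    diss <- min(diss, solid / dt)
    solid <- solid - dt * diss
    dissolved <- dissolved + dt * (diss - perm)
    receiver <- receiver + dt * (perm - coll)
    collected <- collected + dt * coll
    if (solid < 0) { dissolved <- dissolved + solid; solid <- 0 }
    if (dissolved < 0) { receiver <- receiver + dissolved; dissolved <- 0 }
  }
  c(solid = solid, dissolved = dissolved, receiver = receiver,
    collected = collected)
}
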
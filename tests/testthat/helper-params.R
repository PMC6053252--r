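# shared fixtures: the two standard drives used throughout
full_drive <- function(...) neuron_params(g_SynE = 0.5, g_SynI = 1, ...)
reduced_drive <- function(...) neuron_params(g_SynE = 3, g_SynI = 5,
                                             instantaneous_a = TRUE, ...)

# dense-grid oracle for the left knee: two-stage scan, independent of the
# bracketed optimizer in find_knee()
knee_oracle_left <- function(b, s_E, s_I, g_A, params,
                             V_range = c(-75, -15)) {
  br <- function(V) nullcline_branch(V, b, s_E, s_I, g_A, params)
  Vg <- seq(V_range[1], V_range[2], by = 0.25)
  ng <- br(Vg)
  ok <- !is.na(ng)
  last <- if (all(ok)) length(ok) else which(!ok)[1] - 1
  ng <- ng[seq_len(last)]; Vg <- Vg[seq_len(last)]
  i <- which.min(ng)
  if (i == 1 || i == length(ng)) return(NULL)   # no interior fold
  Vf <- seq(Vg[i] - 0.3, Vg[i] + 0.3, by = 0.001)
  nf <- br(Vf)
  min(nf, na.rm = TRUE)
}
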
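# One-off calibration of EPS_SCALE (the overall contact-strength scale in
# make_forcefield.R): a generic 50-residue chain of typical disordered
# composition should reproduce the empirical Flory size 2.54 * N^0.52.
# Run after editing EPS_SCALE in make_forcefield.R; the chosen value is
# then frozen there. Uses a fixed generic sequence (seeded scramble of a
# typical IDP composition).

library(idpsim)

comp <- c(S = 5, P = 5, E = 5, A = 3, G = 4, T = 3, K = 4, D = 3, Q = 2,
          R = 2, N = 2, L = 3, V = 2, I = 2, F = 1, Y = 1, M = 1, H = 1,
          C = 1)
stopifnot(sum(comp) == 50)
letters50 <- rep(names(comp), comp)
set.seed(42)
generic <- paste(sample(letters50), collapse = "")
cat("generic 50-mer:", generic, "\n")

ff <- default_forcefield("high_pH", salt_mM = 150)
top <- build_chain(assign_protonation(generic, "high_pH"), ff)
ens <- run_replicates(top, ff, n_replicates = 3, base_seed = 100,
                      n_steps = 3e6, output_every = 1000)
s <- summarize_rg(ens, equilibration_steps = 6e5)
cat(sprintf("mean Rg = %.2f +/- %.2f A (Flory ref %.2f A)\n",
            s$mean_rg, s$rg_sd, flory_rg(50)))
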
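library(flexattractor)
pop <- ideal_grid_population(100, spacing = 0.6, phase_layout = "uniform",
                             noise_sd = 0.06, seed = 7)
cloud <- build_population_cloud(pop, k = 10)
R <- flexattractor:::cpp_enclosing_radius(cloud$dist)
cat("enclosing radius:", R, "\n")
t0 <- proc.time()
ps <- rips_persistence(cloud, max_degree = 2, field = 2, threshold = 0.8 * R)
cat("0.8R time:", (proc.time()-t0)[3], "s\n")
print(ps)
co <- flexattractor:::diagram_cutoffs(ps)
cat("betti:", count_betti(ps, co), "\n")
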
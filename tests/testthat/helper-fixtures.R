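# Shared fixtures, built in code.

# minimal two-marker panel for hand-constructed tables
tiny_panel <- function() {
  marker_panel(c("GENE1_AF", "GENE2_CN"), c("GENE1", "GENE2"), c("AF", "CN"))
}

write_tiny_csv <- function(lines) {
  f <- tempfile(fileext = ".csv")
  writeLines(lines, f)
  f
}

# noise-free / noisy simulated panels with p spanning (0, 1)
sim_panel <- function(seed = 1, sigma_af = 0.011, sigma_cn = 0.10,
                      n = 47, uniform = TRUE, ...) {
  fd <- if (uniform) "uniform" else
    list(non_cisplatin = c(mean = 0.70, sd = 0.10),
         cisplatin = c(mean = 0.43, sd = 0.15))
  simulate_two_subclone_panel(simulation_config(
    n_samples = n, sigma_af = sigma_af, sigma_cn = sigma_cn,
    fraction_distribution = fd, seed = seed, ...))
}

# genes whose integer genotype is identifiable from the default panel
# (an AF+CN pair, or a CN-only total with no mutation assay)
identifiable_genes <- function() {
  c("LRP1B", "ERBB4", "EPHA3", "EPHA5", "PTPRD", "AR", "EXOC4", "AKR1B1")
}

# TRUE when the called genotypes match the generator's truth on every
# identifiable gene present in the calls
genotypes_recovered <- function(calls, truth_genotypes = default_genotypes()) {
  g1 <- truth_genotypes$subclone1
  g2 <- truth_genotypes$subclone2
  genes <- intersect(identifiable_genes(), calls$gene)
  all(vapply(genes, function(g) {
    i <- match(g, calls$gene)
    j <- match(g, g1$locus)
    calls$m1[i] == g1$m[j] && calls$t1[i] == g1$t[j] &&
      calls$m2[i] == g2$m[j] && calls$t2[i] == g2$t[j]
  }, logical(1)))
}
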
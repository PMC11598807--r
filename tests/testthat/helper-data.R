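# shared builders for planted-structure datasets

ope_panel <- function() default_panel()[default_panel()$family == "OPE", ]

# p x m gamma-shaped sparse-ish profiles, rows normalised by planted_sources
random_profiles <- function(p, m, seed) {
  set.seed(seed)
  matrix(rgamma(p * m, shape = 0.5), p, m)
}

planted_sim <- function(n = 200, p = 3, noise_cv = 0.1, seed = 5,
                        panel = ope_panel()) {
  src <- planted_sources(random_profiles(p, nrow(panel), seed + 100),
                         noise_cv = noise_cv)
  gen_concentrations(n, src, panel, seed = seed)
}

# tiny concentration matrix from a plain matrix over the first congeners
quick_conc <- function(values, panel = default_panel()) {
  values <- as.matrix(values)
  pan <- panel[seq_len(ncol(values)), , drop = FALSE]
  colnames(values) <- pan$name
  conc_matrix(values, panel = pan)
}

write_conc_csv <- function(df, path = tempfile(fileext = ".csv")) {
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}
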
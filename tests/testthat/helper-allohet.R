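# Reference accession coefficients of the two allometries, used as the
# generative truth throughout the tests.
ACC_GROWTH <- c(a = 0.022, b = 1.483, c = -0.164)
ACC_FRUIT <- c(a = 0.155, b = 0.0022, c = 1.292e-5)

g_ref <- function(M, p = ACC_GROWTH) p[["a"]] * M^(p[["b"]] + p[["c"]] * log10(M))
f_ref <- function(M, p = ACC_FRUIT) M / (p[["a"]] + p[["b"]] * M + p[["c"]] * M^2)

mass_grid <- function(n = 200, lo = 0.3, hi = 3.2) 10^seq(lo, hi, length.out = n)

growth_model_ref <- function() list(form = "power_mass_corrected",
                                    coefficients = ACC_GROWTH)
fruit_model_ref <- function() list(form = "inverse_quadratic",
                                   coefficients = ACC_FRUIT)

# small replicate-level table built by hand
make_records <- function(genotype_id, type, parent1 = NA, parent2 = NA,
                         mass, growth = NULL, fruit = NULL) {
  n <- length(mass)
  if (is.null(growth)) growth <- g_ref(mass)
  if (is.null(fruit)) fruit <- f_ref(mass)
  data.frame(genotype_id = rep_len(genotype_id, n),
             type = rep_len(type, n),
             parent1 = rep_len(parent1, n), parent2 = rep_len(parent2, n),
             experiment = "Exp1", replicate = seq_len(n),
             mass_mg = mass, age_d = mass / growth,
             growth_mg_per_d = growth, fruit_n = fruit,
             stringsAsFactors = FALSE)
}
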
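fx <- rsc_fixtures()
sample_ids <- fx$ingredients$sample_id

# numeric per-lot values of one component row from a wide fixture table
row_values <- function(tab, comp) {
  as.numeric(tab[tab$component == comp, sample_ids])
}

# dietary concentration of a component in g/kg DM, per test diet
diet_conc_dm <- function(col) {
  d <- fx$diets[match(sample_ids, fx$diets$diet_id), ]
  to_dm_basis(d[[col]], d$dm) * 10
}

# absolute-tolerance comparison (testthat's tolerance= is relative)
expect_near <- function(actual, expected, tol, label = NULL) {
  expect_lt(max(abs(actual - expected)), tol + 1e-12, label = label)
}

# a tiny valid digesta table for schema tests
small_digesta <- function() {
  aa <- tolower(aa_components())
  df <- data.frame(pig_id = c("P01", "P02"), period = c(1L, 2L),
                   diet_id = c("RSC1", "NFREE"),
                   marker_g_kg_dm = c(8.4, 9.1), cp = c(60.2, 25.1),
                   stringsAsFactors = FALSE)
  for (a in aa) df[[a]] <- c(2.5, 0.4)
  df
}
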
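# fixtures are built in code; nothing is read from disk except what the
# tests themselves write to tempdirs

toy_plot_table <- function(n = 6L, seed = 1L) {
  set.seed(seed)
  plot_table(data.frame(
    plot_id = sprintf("T%02d", seq_len(n)),
    lon = 113.3 + seq_len(n) * 0.01,
    lat = 38.95 + seq_len(n) * 0.005,
    elevation = seq(2000, 3000, length.out = n),
    environment = rep(c("grassland", "forest"), length.out = n),
    Bio1 = seq(2, -4, length.out = n), Bio6 = seq(-20, -26, length.out = n),
    Bio7 = seq(40, 42, length.out = n), Bio12 = seq(600, 760, length.out = n),
    Bio14 = seq(10, 14, length.out = n), WS = seq(3, 4, length.out = n),
    NPP = seq(0.3, 0.5, length.out = n), NDVI = seq(0.35, 0.45, length.out = n),
    HD = rep(2, n), stringsAsFactors = FALSE))
}

toy_occurrence <- function(plots, n_species = 4L, area = 100, fill = 1L) {
  m <- matrix(fill, nrow(plots), n_species,
              dimnames = list(plots$plot_id,
                              sprintf("sp%02d", seq_len(n_species))))
  occurrence_matrix(m, area, plots = plots)
}

# deterministic small synthetic world shared by several tests
small_world <- function(seed = 1L, n_plots = 30L) {
  plots <- generate_environment(n_plots = n_plots, seed = seed)
  truth <- synthetic_truth(seed = seed)
  occ <- generate_community(plots, truth, seed = seed)
  list(plots = plots, truth = truth, occ = occ)
}
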
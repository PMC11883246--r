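# Small simulation configs shared across tests.

small_config <- function(seed = 1L, ...) {
  defaults <- list(
    n_cells = 400, n_clusters = 4, n_target_genes = 3, guides_per_gene = 2,
    n_scramble = 2, n_background_genes = 4,
    guides_per_cell = list(mean = 1.5, max = 10, zero_prob = 0.3),
    seed = seed
  )
  args <- utils::modifyList(defaults, list(...))
  do.call(simulation_config, args)
}

# Assignment set from a hand-built cells x guides matrix (all counts equal,
# so nothing is discarded): convenient for constructing exact scenarios.
manual_assignments <- function(cell_guide_pairs, library, cells = NULL) {
  if (is.null(cells)) cells <- sort(unique(cell_guide_pairs$cell_id))
  m <- matrix(0, length(cells), nrow(library),
              dimnames = list(cells, library$guide_id))
  m[cbind(match(cell_guide_pairs$cell_id, cells),
          match(cell_guide_pairs$guide_id, library$guide_id))] <- 10
  filter_ambient(m, library)
}
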
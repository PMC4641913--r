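# Small in-code fixtures shared across test files.

# A tiny deterministic count matrix: 4 genes, one baseline library plus
# pond/upland pairs at 2 time points, with hand-chosen counts.
tiny_count_matrix <- function() {
  counts <- rbind(
    gA = c(10, 40, 10, 80, 10),
    gB = c(5, 5, 5, 5, 5),
    gC = c(0, 0, 12, 0, 9),
    gD = c(1, 1, 0, 1, 1))
  colnames(counts) <- c("baseline_0h", "pond_1h", "upland_1h",
                        "pond_3h", "upland_3h")
  meta <- data.frame(
    library_id = colnames(counts),
    condition = c("baseline", "pond", "upland", "pond", "upland"),
    time_h = c(0, 1, 1, 3, 3))
  count_matrix(counts, c(gA = 1000, gB = 500, gC = 2000, gD = 800), meta)
}

# Small but complete synthetic run used by several stage tests.
small_sim <- function(seed = 101, n_genes = 1200, ...) {
  simulate_timecourse(sim_config(n_genes = n_genes, seed = seed, ...))
}
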
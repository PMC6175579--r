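# Shared synthetic fixtures, built lazily and cached for the whole run.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixtures)) {
    assign(name, builder(), envir = .fixtures)
  }
  get(name, envir = .fixtures)
}

# Small genome + pool used by many IO / annotation tests.
tiny_genome <- function() {
  fixture("tiny_genome", function() sim_genome(20, 8e4, seed = 7))
}

tiny_pool <- function() {
  fixture("tiny_pool", function() sim_pool(tiny_genome(), 400, seed = 7))
}

# Mid-scale full-design simulation with planted effects: 500 genes x 16
# central insertions, 5 conditions x 3 timepoints x 3 replicates, depth 4e5.
mid_sim <- function() {
  fixture("mid_sim", function() {
    genome <- sim_genome(500, 1.3e6, seed = 99)
    pool <- sim_pool(genome, central_per_gene = 16, seed = 99)
    design <- sim_design(depth = 4e5, seed = 99)
    truth <- sim_truth(genome, design, effect = -3, seed = 99)
    counts <- sim_counts(pool, truth, design, genome = genome)
    fit <- run_fitness(counts, pool, genome = genome)
    list(genome = genome, pool = pool, design = design, truth = truth,
         counts = counts, fit = fit)
  })
}

# Random disjoint-ish gene sets for set-algebra property tests.
random_sets <- function(n_genes = 60, n_sets = 4, p = 0.3) {
  genes <- sprintf("g%03d", seq_len(n_genes))
  lapply(seq_len(n_sets), function(i) genes[runif(n_genes) < p])
}
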
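# Shared fixtures, all built in code.

default_table <- local({
  tab <- NULL
  function() {
    if (is.null(tab)) tab <<- load_type_table()
    tab
  }
})

# the canonical RING-H2 demonstration sequence: ligands at
# 0,3,13,15,18,21,26,29 (0-based), all spacers alanine
h2_demo_sequence <- function(s45 = 2L) {
  paste0("C", "AA", "C", strrep("A", 9), "C", "A", "H",
         strrep("A", s45), "H", "AA", "C", strrep("A", 4), "C", "AA", "C")
}

rec <- function(id, sequence) list(id = id, description = id,
                                   sequence = sequence)

random_protein <- function(n = 150, enrich_ch = FALSE) {
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  w <- rep(1, 20)
  if (enrich_ch) w[aa %in% c("C", "H")] <- 6
  paste(sample(aa, n, TRUE, prob = w), collapse = "")
}

# a small proteome reused across catalog/motif tests
small_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- make_proteome(sim_spec(seed = 42), default_table())
    }
    cache
  }
})

expect_same_hits <- function(a, b) {
  expect_identical(as.data.frame(a), as.data.frame(b))
}
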
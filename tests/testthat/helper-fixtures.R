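# shared fixtures, built in code at test time

tiny_taxonomy <- function() build_taxonomy(3, 2)

tiny_markers <- function(tax = tiny_taxonomy(), seed = 7) {
  simulate_markers(tax, markers_per_genus = 1, length_range = c(300, 400),
                   seed = seed)
}

# a kmer_distribution from explicit masses (for EMD unit tests)
kdist <- function(mass, k = nchar(names(mass)[1])) {
  structure(list(k = k, mass = mass / sum(mass), canonical = FALSE),
            class = "kmer_distribution")
}

# random k-mer distribution with bounded support
random_kdist <- function(k = 4, max_support = 8) {
  s <- max(2, sample.int(max_support, 1))
  kmers <- unique(random_dna_strings(s, k))
  m <- runif(length(kmers)) + 0.05
  kdist(setNames(m / sum(m), kmers), k)
}

random_dna_strings <- function(n, len) {
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = ""),
    character(1))
}

# dense-LP earth mover's distance oracle via scipy (HiGHS); `problems` is a
# list of lists with fields a, b (masses) and cost (matrix). Returns the
# optimal transport costs.
emd_lp_oracle <- function(problems) {
  script <- system.file("oracle", "emd_lp.py", package = "bloodbiome")
  stopifnot(nzchar(script))
  fin <- tempfile(fileext = ".json")
  fout <- tempfile(fileext = ".json")
  jsonlite::write_json(
    lapply(problems, function(p)
      list(a = p$a, b = p$b, cost = p$cost)),
    fin, digits = NA, matrix = "rowmajor")
  status <- system2("python", c(script, fin, fout))
  stopifnot(status == 0)
  as.numeric(unlist(jsonlite::read_json(fout)))
}

# small synthetic sample for filter/profiler oracles
mini_sample <- function(n_reads = 5000, seed = 11, error_rate = 0,
                        knobs = list()) {
  tax <- build_taxonomy(5, 2)
  markers <- simulate_markers(tax, 2, length_range = c(300, 600), seed = seed)
  host <- simulate_host_reference(seed = seed + 1)
  profile <- group_profile("G", setNames(rep(0.5, 10), tax_genera(tax)))
  ab <- draw_sample_abundances(profile, seed = seed + 2)
  kb <- modifyList(list(n_reads = n_reads, error_rate = error_rate), knobs)
  sim <- simulate_sample_reads("s1", ab, markers, host, kb, seed = seed + 3)
  list(tax = tax, markers = markers, host = host, abundances = ab, sim = sim)
}
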
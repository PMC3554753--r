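# shared fixtures, built in code and memoized for the whole test run

tiny_depths <- c("10DAF" = 2000L, "15DAF" = 2000L, "21DAF" = 2000L,
                 "27DAF" = 2000L, "35DAF" = 2000L)

tiny_config <- function(seed = 7L, ...) {
  simulation_config(genome_length = 20000L, n_known_mirnas = 4L,
                    n_novel_hairpins = 3L, n_target_genes = 5L,
                    n_decoy_genes = 3L, library_depths = tiny_depths,
                    noise_dispersion = 0, seed = seed, ...)
}

.cache <- new.env(parent = emptyenv())

# noise-free simulated world shared by annotation / discovery / acceptance
shared_world <- function() {
  if (is.null(.cache$world)) {
    cfg <- tiny_config()
    sim <- simulate_genome(cfg)
    libs <- simulate_libraries(sim$genome, sim$truth, cfg)
    hits <- map_to_genome(libs$sequence, sim$genome)
    cls <- classify_reads(libs, hits, sim$tracks)
    .cache$world <- list(cfg = cfg, sim = sim, libs = libs, hits = hits,
                         cls = cls,
                         totals = colSums(mirfill:::count_matrix(libs)))
  }
  .cache$world
}

shared_discovery <- function() {
  if (is.null(.cache$disc)) {
    w <- shared_world()
    .cache$disc <- discover_novel_mirnas(w$cls, w$hits, w$sim$genome,
                                         tracks = w$sim$tracks,
                                         totals = w$totals)
  }
  .cache$disc
}

# mutate a perfect-complement site so that the duplex has the given state
# at the given miRNA positions ("MM" or "GU")
make_site <- function(mirna, mm_at = integer(0), gu_at = integer(0)) {
  mirna <- mirfill:::norm_seq(mirna)
  L <- nchar(mirna)
  site <- strsplit(mirfill:::revcomp(mirna), "")[[1]]
  mch <- strsplit(mirna, "")[[1]]
  mm_base <- c(A = "A", C = "C", G = "A", T = "T")  # always a mismatch
  for (k in mm_at) site[L - k + 1] <- mm_base[[mch[k]]]
  for (k in gu_at) {
    # wobble needs G or U on the miRNA side at that position
    stopifnot(mch[k] %in% c("G", "T"))
    site[L - k + 1] <- if (mch[k] == "G") "T" else "G"
  }
  paste(site, collapse = "")
}

# adjusted Rand index between two partitions (independent oracle helper)
adjusted_rand <- function(x, y) {
  tab <- table(x, y)
  a <- sum(choose(tab, 2))
  b <- sum(choose(rowSums(tab), 2))
  cc <- sum(choose(colSums(tab), 2))
  n <- sum(tab)
  expected <- b * cc / choose(n, 2)
  maxi <- (b + cc) / 2
  (a - expected) / (maxi - expected)
}
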
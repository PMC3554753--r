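#' Configuration of the synthetic grain-filling study
#'
#' The generator emulates the design of the five-stage study: five
#' stage-labelled small-RNA libraries (10/15/21/27/35 DAF) from a toy
#' genome carrying rRNA/tRNA/snRNA/snoRNA loci, repeats, genes with
#' exons and introns, known miRNA hairpins and novel (untracked)
#' hairpins.  Default library depths mirror the study's library totals
#' scaled down 1000-fold; the default profile templates emulate the four
#' major expression clusters (gradual rise, early peak, dip-then-rise,
#' mid-peak) plus a flat profile.
#'
#' @param genome_length genome size in bases.
#' @param n_known_mirnas,n_novel_hairpins,n_target_genes,n_decoy_genes
#'   feature counts.
#' @param library_depths named integer vector stage -> total read count.
#' @param profile_templates named list of 5-vectors of relative abundance
#'   (one entry per stage), assigned to planted miRNAs cyclically.
#' @param noise_dispersion negative-binomial dispersion of planted counts
#'   (0 = deterministic rounded means).
#' @param mirna_abundance expected fraction of a library taken by one
#'   planted miRNA at template value 1.
#' @param star_ratios per-species star:mature emission ratios, recycled;
#'   the default plants one strongly star-dominant species (ratio 50,
#'   emulating the most extreme star excess reported) and one mildly
#'   dominant (1.5) besides the usual 0.1.
#' @param seed integer; fully determines all outputs.
#' @return validated list of class `"simulation_config"`.
#' @export
simulation_config <- function(genome_length = 50000L,
                              n_known_mirnas = 8L,
                              n_novel_hairpins = 6L,
                              n_target_genes = 6L,
                              n_decoy_genes = 4L,
                              library_depths = c("10DAF" = 14249L, "15DAF" = 13297L,
                                                 "21DAF" = 11379L, "27DAF" = 11648L,
                                                 "35DAF" = 10658L),
                              profile_templates = list(
                                rise      = c(0.2, 0.4, 0.6, 0.8, 1.0),
                                early_peak = c(0.5, 1.0, 0.8, 0.6, 0.5),
                                dip_rise  = c(1.0, 0.6, 0.4, 0.5, 0.9),
                                mid_peak  = c(0.3, 0.7, 1.0, 0.4, 0.8),
                                flat      = c(1, 1, 1, 1, 1)),
                              noise_dispersion = 0.05,
                              mirna_abundance = 0.01,
                              star_ratios = NULL,
                              seed = 1L) {
  if (any(library_depths <= 0)) stop("library depths must be positive")
  if (is.null(names(library_depths))) names(library_depths) <- STAGES
  bad <- vapply(profile_templates,
                function(p) length(p) != length(library_depths) || any(p < 0),
                logical(1))
  if (any(bad)) stop("each profile template needs ", length(library_depths),
                     " non-negative entries")
  if (noise_dispersion < 0) stop("noise_dispersion must be >= 0")
  n_species <- n_known_mirnas + n_novel_hairpins
  if (is.null(star_ratios)) {
    star_ratios <- rep(0.1, max(n_species, 1L))
    if (n_species >= 1) star_ratios[1] <- 50
    if (n_species >= 2) star_ratios[2] <- 1.5
  }
  structure(list(genome_length = as.integer(genome_length),
                 n_known_mirnas = as.integer(n_known_mirnas),
                 n_novel_hairpins = as.integer(n_novel_hairpins),
                 n_target_genes = as.integer(n_target_genes),
                 n_decoy_genes = as.integer(n_decoy_genes),
                 library_depths = library_depths,
                 profile_templates = profile_templates,
                 noise_dispersion = noise_dispersion,
                 mirna_abundance = mirna_abundance,
                 star_ratios = rep_len(star_ratios, max(n_species, 1L)),
                 # keep room for derived seeds below .Machine$integer.max
                 seed = as.integer(as.numeric(seed) %% 2e9)),
            class = "simulation_config")
}

# evaluate code under a seed without leaking RNG state
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

rand_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                              collapse = "")

# mature + loop + reverse complement: folds into a perfect stem-loop whose
# mature:star duplex trivially satisfies the MIREAP criteria
make_hairpin <- function(mature_len = 21L, loop_len = 9L) {
  mature <- rand_seq(mature_len)
  loop <- rand_seq(loop_len)
  star <- revcomp(mature)
  list(seq = paste0(mature, loop, star), mature = mature, star = star,
       mature_off = c(0L, mature_len),
       star_off = c(mature_len + loop_len, mature_len + loop_len + mature_len))
}

#' Simulate a toy genome with planted annotation tracks and ground truth
#'
#' Features are placed left to right with random intergenic gaps:
#' rRNA/tRNA/snRNA/snoRNA loci (GenBank-like and Rfam-like sources),
#' repeats, genes with exons and introns, known miRNA hairpins (tracked)
#' and novel hairpins (absent from the known-miRNA track).  All hairpins
#' are perfect inverted repeats, so they fold far below the -18 kcal/mol
#' precursor cutoff under the package energy model.
#'
#' @param config a [simulation_config()].
#' @return list with `genome` (named character, one chromosome), `tracks`
#'   (an [annotation_tracks()]), and `truth` (list: `planted_mirnas`
#'   data.frame, `profiles` templates per species, `config`).
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  with_seed(config$seed, {
    feats <- list()
    add <- function(type, len, id, source = NA, parent = NA) {
      feats[[length(feats) + 1L]] <<- list(type = type, len = len, id = id,
                                           source = source, parent = parent)
    }
    add("rRNA", 300L, "rrna1", "genbank"); add("rRNA", 280L, "rrna2", "rfam")
    add("tRNA", 75L, "trna1", "genbank");  add("tRNA", 75L, "trna2", "rfam")
    add("snRNA", 110L, "snrna1", "rfam");  add("snoRNA", 100L, "snorna1", "rfam")
    for (i in 1:4) add("repeat", 250L, paste0("rep", i))
    genes <- 4L
    hp_len <- 21L + 9L + 21L
    n_feat_bases <- 300 + 280 + 75 + 75 + 110 + 100 + 4 * 250 +
      genes * (200 + 120 + 200) +
      (config$n_known_mirnas + config$n_novel_hairpins) * hp_len
    if (n_feat_bases * 1.3 > config$genome_length) {
      stop("feature demand exceeds genome capacity; increase genome_length")
    }

    rows <- list(); pieces <- list(); pos <- 0L
    truth_rows <- list()
    gap <- function() {
      g <- sample(100:400, 1)
      pieces[[length(pieces) + 1L]] <<- rand_seq(g)
      pos <<- pos + g
    }
    put <- function(seq) {
      s <- pos
      pieces[[length(pieces) + 1L]] <<- seq
      pos <<- pos + nchar(seq)
      c(s, pos)
    }
    feat_row <- function(type, span, id, source = NA, parent = NA,
                         strand = "+") {
      rows[[length(rows) + 1L]] <<- data.frame(
        type = type, chrom = "chr1", start = span[1], end = span[2],
        strand = strand, id = id, source = source, parent = parent,
        stringsAsFactors = FALSE)
    }

    for (f in feats) {
      gap()
      span <- put(rand_seq(f$len))
      feat_row(f$type, span, f$id, f$source, f$parent)
    }
    # genes: exon - intron - exon, alternating strand
    for (g in seq_len(genes)) {
      gap()
      strand <- if (g %% 2 == 0) "-" else "+"
      gid <- paste0("gene", g)
      e1 <- put(rand_seq(200L)); i1 <- put(rand_seq(120L)); e2 <- put(rand_seq(200L))
      feat_row("gene", c(e1[1], e2[2]), gid, strand = strand)
      feat_row("exon", e1, paste0(gid, ".e1"), parent = gid, strand = strand)
      feat_row("intron", i1, paste0(gid, ".i1"), parent = gid, strand = strand)
      feat_row("exon", e2, paste0(gid, ".e2"), parent = gid, strand = strand)
    }
    templates <- names(config$profile_templates)
    n_species <- config$n_known_mirnas + config$n_novel_hairpins
    for (i in seq_len(n_species)) {
      gap()
      known <- i <= config$n_known_mirnas
      hp <- make_hairpin()
      span <- put(hp$seq)
      id <- if (known) paste0("osa-miRsim", i) else paste0("novelsim", i)
      if (known) {
        feat_row("mirna_precursor", span, id)
        feat_row("mirna_mature", span[1] + hp$mature_off, paste0(id, "-5p"),
                 parent = id)
        feat_row("mirna_star", span[1] + hp$star_off, paste0(id, "-3p"),
                 parent = id)
      }
      truth_rows[[length(truth_rows) + 1L]] <- data.frame(
        id = id, known = known, chrom = "chr1",
        prec_start = span[1], prec_end = span[2], strand = "+",
        mature = hp$mature, star = hp$star,
        mature_start = span[1] + hp$mature_off[1],
        mature_end = span[1] + hp$mature_off[2],
        star_start = span[1] + hp$star_off[1],
        star_end = span[1] + hp$star_off[2],
        profile = templates[(i - 1L) %% length(templates) + 1L],
        star_ratio = config$star_ratios[i],
        stringsAsFactors = FALSE)
    }
    if (pos < config$genome_length) {
      pieces[[length(pieces) + 1L]] <- rand_seq(config$genome_length - pos)
    }
    genome <- c(chr1 = paste(pieces, collapse = ""))
    tracks <- annotation_tracks(do.call(rbind, rows))
    spans <- lapply(split(tracks[, c("start", "end")], tracks$type),
                    as.data.frame)
    truth <- list(
      planted_mirnas = if (length(truth_rows)) do.call(rbind, truth_rows) else
        data.frame(),
      profiles = config$profile_templates,
      feature_spans = spans,
      logistic_params = c(K = 20, a = 100, b = 0.2),
      config = config)
    list(genome = genome, tracks = tracks, truth = truth)
  })
}

# negative-binomial multiplicative noise around a mean; dispersion 0 is
# the deterministic noise-free case (counts = rounded means, so planted
# counts are exactly proportional to template x depth)
noisy_count <- function(mu, dispersion) {
  if (dispersion <= 0 || mu == 0) return(as.integer(round(mu)))
  as.integer(stats::rnbinom(1, mu = mu, size = 1 / dispersion))
}

#' Simulate the five stage-labelled small-RNA libraries
#'
#' Planted mature counts follow `template[stage] * depth[stage] *
#' mirna_abundance` with negative-binomial noise of the configured
#' dispersion; star reads are emitted at each species' star:mature ratio;
#' the remainder of each library is background sampled from the non-miRNA
#' tracks and intergenic space with a 24-nt-dominant length distribution.
#' Per-stage totals equal the configured depths exactly.
#'
#' @param genome,truth from [simulate_genome()].
#' @param config the same [simulation_config()].
#' @return a [collapse_reads()]-style data.frame (`sequence` + one count
#'   column per stage) with attribute `depths`.
#' @export
simulate_libraries <- function(genome, truth, config) {
  stopifnot(inherits(config, "simulation_config"))
  with_seed(config$seed + 1L, {
    depths <- config$library_depths
    stages <- names(depths)
    pm <- truth$planted_mirnas
    chunks <- list()
    for (s in stages) {
      planted_total <- 0L
      if (nrow(pm)) for (i in seq_len(nrow(pm))) {
        tpl <- config$profile_templates[[pm$profile[i]]]
        mu <- tpl[match(s, stages)] * depths[[s]] * config$mirna_abundance
        n_mat <- noisy_count(mu, config$noise_dispersion)
        n_star <- as.integer(round(pm$star_ratio[i] * n_mat))
        if (n_mat > 0) chunks[[length(chunks) + 1L]] <- data.frame(
          sequence = pm$mature[i], stage = s, count = n_mat)
        if (n_star > 0) chunks[[length(chunks) + 1L]] <- data.frame(
          sequence = pm$star[i], stage = s, count = n_star)
        planted_total <- planted_total + n_mat + n_star
      }
      n_bg <- depths[[s]] - planted_total
      if (n_bg < 0) stop("planted reads exceed library depth at stage ", s)
      bg <- sample_background(genome, truth, n_bg)
      if (length(bg)) {
        tab <- table(bg)
        chunks[[length(chunks) + 1L]] <- data.frame(
          sequence = names(tab), stage = s, count = as.integer(tab))
      }
    }
    reads <- do.call(rbind, chunks)
    out <- collapse_reads(reads, stages = stages)
    attr(out, "depths") <- depths
    out
  })
}

# background reads: feature class sampled with Table-1-like weights, then
# a random substring of a feature of that class (or intergenic space)
sample_background <- function(genome, truth, n) {
  if (n <= 0) return(character(0))
  gseq <- genome[[1]]
  glen <- nchar(gseq)
  classes <- c(rRNA = 0.11, tRNA = 0.035, snRNA = 0.0005, snoRNA = 0.0005,
               "repeat" = 0.28, exon = 0.115, intron = 0.065, intergenic = 0.394)
  lens <- 18:30
  lprob <- c(0.02, 0.02, 0.03, 0.22, 0.04, 0.05, 0.50, 0.04, 0.03, 0.02,
             0.01, 0.01, 0.01)
  cls <- sample(names(classes), n, replace = TRUE, prob = classes)
  rl <- sample(lens, n, replace = TRUE, prob = lprob)
  strand <- sample(c("+", "-"), n, replace = TRUE)
  feats <- truth$feature_spans
  starts <- integer(n)
  for (i in seq_len(n)) {
    sp <- feats[[cls[i]]]
    if (is.null(sp)) {
      starts[i] <- sample.int(glen - rl[i], 1) - 1L
    } else {
      j <- sample.int(nrow(sp), 1)
      lo <- sp$start[j]; hi <- sp$end[j]
      starts[i] <- if (hi - lo < rl[i]) sample.int(glen - rl[i], 1) - 1L
                   else lo + sample.int(hi - lo - rl[i] + 1L, 1) - 1L
    }
  }
  frags <- substring(gseq, starts + 1L, starts + rl)
  neg <- strand == "-"
  if (any(neg)) frags[neg] <- revcomp(frags[neg])
  frags
}

#' Simulate a grain-weight time series from the logistic model
#'
#' `weight(t) = K / (1 + a exp(-b t)) + N(0, noise_sd)`.
#'
#' @param params numeric vector or list with elements `K`, `a`, `b`
#'   (all > 0).
#' @param days DAF sampling times.
#' @param noise_sd Gaussian noise standard deviation in mg (default 0.3,
#'   a realistic per-kernel weighing error).
#' @param seed optional RNG seed.
#' @return data.frame `daf`, `weight` (mg).
#' @export
simulate_grain_weights <- function(params, days, noise_sd = 0.3, seed = NULL) {
  K <- params[["K"]]; a <- params[["a"]]; b <- params[["b"]]
  if (any(c(K, a, b) <= 0)) stop("K, a and b must be positive")
  gen <- function() {
    w <- K / (1 + a * exp(-b * days))
    if (noise_sd > 0) {
      # dry weights cannot be negative; floor the measurement
      w <- pmax(w + stats::rnorm(length(days), 0, noise_sd), 0.01)
    }
    data.frame(daf = days, weight = w)
  }
  if (is.null(seed)) gen() else with_seed(seed, gen())
}

#' Simulate target transcripts and DGE tag libraries
#'
#' Each planted target transcript embeds a perfect-complement site of its
#' miRNA (which satisfies all six target-prediction rules by
#' construction) and at least one CATG site with 17 nt downstream.
#' Target-gene abundance across stages is coupled to the miRNA profile
#' with configurable sign (coupling -1: the planted per-stage profiles
#' have Pearson correlation exactly -1); decoy genes get independent
#' random profiles.  Tag libraries emit each transcript's 3'-most
#' canonical tag at the gene's (noisy) count, plus singleton junk tags
#' that the tag filter must remove.
#'
#' @param truth from [simulate_genome()].
#' @param config the same [simulation_config()].
#' @param coupling -1 (repression, default) or +1.
#' @param base_count expected tag count of a gene at profile value 1.
#' @param n_junk_tags singleton tags added per stage.
#' @return list: `transcripts` (named character), `tags` (data.frame
#'   `tag`, `stage`, `count`), `pairs` (miRNA-gene pairs with planted site
#'   coordinates), `gene_profiles` (planted per-stage relative profiles),
#'   `mirna_profiles`.
#' @export
simulate_dge <- function(truth, config, coupling = -1, base_count = 200,
                         n_junk_tags = 3L) {
  stopifnot(inherits(config, "simulation_config"))
  pm <- truth$planted_mirnas
  if (!nrow(pm)) stop("no planted miRNAs; cannot plant targets")
  with_seed(config$seed + 2L, {
    stages <- names(config$library_depths)
    n_t <- config$n_target_genes; n_d <- config$n_decoy_genes
    transcripts <- character(0); pairs <- list()
    gene_prof <- list(); mir_prof <- list()
    for (g in seq_len(n_t)) {
      mi <- (g - 1L) %% nrow(pm) + 1L
      site <- revcomp(pm$mature[mi])
      up <- rand_seq(80L)
      tx <- paste0(up, site, rand_seq(40L), "CATG", rand_seq(25L))
      gid <- paste0("target", g)
      transcripts[[gid]] <- tx
      pairs[[length(pairs) + 1L]] <- data.frame(
        mirna = pm$id[mi], gene = gid, site_start = 80L,
        site_end = 80L + nchar(site), coupled = TRUE,
        stringsAsFactors = FALSE)
      mp <- config$profile_templates[[pm$profile[mi]]]
      gp <- if (coupling < 0) max(mp) + min(mp) - mp else mp
      gene_prof[[gid]] <- gp / max(gp)
      mir_prof[[pm$id[mi]]] <- mp
    }
    for (g in seq_len(n_d)) {
      gid <- paste0("decoy", g)
      transcripts[[gid]] <- paste0(rand_seq(120L), "CATG", rand_seq(25L))
      gene_prof[[gid]] <- stats::runif(length(stages), 0.2, 1)
    }
    tag_rows <- list()
    for (gid in names(transcripts)) {
      ct <- canonical_tags(transcripts[[gid]])
      primary <- ct$tag[ct$primary]
      for (si in seq_along(stages)) {
        mu <- base_count * gene_prof[[gid]][si]
        cnt <- max(2L, noisy_count(mu, config$noise_dispersion))
        tag_rows[[length(tag_rows) + 1L]] <- data.frame(
          tag = primary, stage = stages[si], count = cnt,
          stringsAsFactors = FALSE)
      }
    }
    for (si in seq_along(stages)) {
      for (j in seq_len(n_junk_tags)) {
        tag_rows[[length(tag_rows) + 1L]] <- data.frame(
          tag = paste0("CATG", rand_seq(17L)), stage = stages[si], count = 1L,
          stringsAsFactors = FALSE)
      }
    }
    list(transcripts = transcripts,
         tags = do.call(rbind, tag_rows),
         pairs = do.call(rbind, pairs),
         gene_profiles = do.call(rbind, gene_prof),
         mirna_profiles = do.call(rbind, mir_prof))
  })
}
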
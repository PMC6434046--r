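# Synthetic PEM-seq library generator.
#
# The generator emulates the library structure of the assay: sonicated
# fragments of 0.3-2 kb, a biotinylated bait primer within 200 bp of the
# cut (read 1 is primer-anchored), a bridge adapter on the far end
# carrying a 14-bp random molecular barcode (read 2 starts with the
# adapter), PCR duplication with per-base substitution errors that also
# hit the barcode, and a stated mixture of repair outcomes.

SIM_CATEGORIES <- c("germline", "small_insertion", "small_deletion",
                    "large_deletion", "inversion",
                    "background_translocation", "offtarget_translocation")

#' Generative parameters for a synthetic PEM-seq library
#'
#' Default values describe the experimental conditions the assay was run
#' under: 2 x 150 bp reads from 0.3-2 kb fragments, a mixture dominated by
#' germline molecules with roughly 37% indels and 2.8% translocations
#' among all molecules, mean PCR duplication 3, and a resection tail
#' placing 0.05% of editing events 5-50 kb downstream of the cut.
#'
#' @param genome_sizes named integer vector of chromosome lengths.
#' @param seed integer seed; the whole library is a deterministic function
#'   of the spec.
#' @param guide 20-nt protospacer written at the bait site.
#' @param mixture named probability vector over molecule categories
#'   (`germline`, `small_insertion`, `small_deletion`, `large_deletion`,
#'   `inversion`, `background_translocation`, optionally
#'   `offtarget_translocation`); must sum to 1.
#' @param offtargets data.table/data.frame with one row per implanted
#'   cryptic site: columns `mismatches` (protospacer mismatch count) and
#'   `pam` (logical for intact NGG, or one of `"NGG"`, `"NAG"`,
#'   `"none"`).
#' @param resection_mass fraction of editing (non-germline) events whose
#'   deletion junction falls 5-50 kb downstream of the cut.
#' @param resection_scale exponential decay scale (bp) of the resection
#'   tail beyond 5 kb.
#' @param n_molecules number of original molecules.
#' @param duplication mean number of extra PCR copies per molecule
#'   (copies are `1 + Poisson(duplication)`).
#' @param error_rate per-base substitution error probability per copy.
#' @param fragment_size two-element range of sonicated fragment lengths.
#' @param read_len read length (150).
#' @param bait_gap distance (bp) from the primer 3' end to the cut; with
#'   the 20-nt primer this keeps the junction well inside read 1.
#' @param ins_range,del_range small-indel size ranges.
#' @return An object of class `sim_spec`.
#' @export
sim_spec <- function(genome_sizes = c(chr1 = 1500000L, chr2 = 1500000L),
                     seed = 1L,
                     guide = "GACTGGAGTTCAGACGTGTG",
                     mixture = c(germline = 0.600,
                                 small_insertion = 0.107,
                                 small_deletion = 0.227,
                                 large_deletion = 0.030,
                                 inversion = 0.008,
                                 background_translocation = 0.028),
                     offtargets = NULL,
                     resection_mass = 5e-4,
                     resection_scale = 10000,
                     n_molecules = 10000L,
                     duplication = 3,
                     error_rate = 0.002,
                     fragment_size = c(300L, 2000L),
                     read_len = 150L,
                     bait_gap = 60L,
                     ins_range = c(1L, 10L),
                     del_range = c(1L, 15L)) {
  if (is.null(names(genome_sizes))) stopf("genome_sizes must be named")
  if (!all(names(mixture) %in% SIM_CATEGORIES))
    stopf("unknown mixture categories: %s",
          paste(setdiff(names(mixture), SIM_CATEGORIES), collapse = ", "))
  if (any(mixture < 0) || abs(sum(mixture) - 1) > 1e-8)
    stopf("mixture must be non-negative and sum to 1")
  if (nchar(guide) != 20L) stopf("guide must be 20 nt")
  if (!is.null(offtargets)) offtargets <- as.data.table(offtargets)
  structure(list(genome_sizes = genome_sizes, seed = as.integer(seed),
                 guide = toupper(guide), mixture = mixture,
                 offtargets = offtargets,
                 resection_mass = resection_mass,
                 resection_scale = resection_scale,
                 n_molecules = as.integer(n_molecules),
                 duplication = duplication, error_rate = error_rate,
                 fragment_size = as.integer(fragment_size),
                 read_len = as.integer(read_len),
                 bait_gap = as.integer(bait_gap),
                 ins_range = as.integer(ins_range),
                 del_range = as.integer(del_range)),
            class = "sim_spec")
}

#' A spec for the matched uncut control library
#'
#' Same genome and settings, but every molecule is germline and a
#' different RNG stream is used.
#'
#' @param spec a [sim_spec()].
#' @param n_molecules optional control library size.
#' @return A `sim_spec` whose mixture is 100\% germline.
#' @export
control_spec <- function(spec, n_molecules = spec$n_molecules) {
  spec$mixture <- c(germline = 1)
  spec$n_molecules <- as.integer(n_molecules)
  spec$seed <- spec$seed + 1000L
  spec
}

# Draw genomic positions uniformly outside the bait exclusion zone and
# away from chromosome ends.
draw_positions <- function(n, genome_sizes, bait_chrom, bait_cut,
                           exclusion = 250000L, margin = 2100L) {
  sizes <- genome_sizes
  chroms <- names(sizes)
  out_chrom <- character(n)
  out_pos <- integer(n)
  w <- sizes - 2 * margin
  for (i in seq_len(n)) {
    repeat {
      ch <- sample(chroms, 1L, prob = w)
      p <- sample.int(sizes[[ch]] - 2L * margin, 1L) + margin
      if (ch != bait_chrom || abs(p - bait_cut) > exclusion) break
    }
    out_chrom[i] <- ch
    out_pos[i] <- p
  }
  list(chrom = out_chrom, pos = out_pos)
}

#' Build a toy genome with implanted target sites
#'
#' Generates random chromosome sequences, writes the on-target
#' protospacer+PAM just upstream of the bait primer anchor, and implants
#' each requested off-target with its exact protospacer mismatch count and
#' PAM state (intact PAMs get `NGG`, broken ones `NTT`). Off-targets are
#' placed outside the bait +/- 250 kb zone with at least 10 kb of
#' separation. Deterministic for a fixed spec.
#'
#' @param spec a [sim_spec()].
#' @return A list with `genome` (named character vector of chromosome
#'   sequences), `bait` (a [bait_config()]), and `offtargets` (data.table
#'   `site_id`, `chrom`, `start`, `strand`, `cut`, `mismatches`, `pam_ok`,
#'   `seq`).
#' @export
make_genome <- function(spec) {
  set.seed(spec$seed)
  genome <- vapply(spec$genome_sizes, random_dna, character(1))
  bait_chrom <- names(spec$genome_sizes)[1]
  cut <- as.integer(spec$genome_sizes[[1]] %/% 2L)

  # on-target: protospacer at [cut-16, cut+3], PAM at [cut+4, cut+6]
  site <- paste0(spec$guide, paste0(sample(DNA_ALPHABET, 1L), "GG"))
  s0 <- cut - 16L
  substr(genome[[bait_chrom]], s0, s0 + 22L) <- site

  primer_len <- 20L
  primer_end <- cut - spec$bait_gap
  primer_start <- primer_end - primer_len + 1L
  bait <- bait_config(bait_chrom, "+", primer_start, primer_end, cut,
                      spec$guide, pam = "NGG")

  ot <- spec$offtargets
  sites <- data.table(site_id = character(0), chrom = character(0),
                      start = integer(0), strand = character(0),
                      cut = integer(0), mismatches = integer(0),
                      pam_ok = logical(0), seq = character(0))
  if (!is.null(ot) && nrow(ot) > 0L) {
    placed <- list(chrom = character(0), pos = integer(0))
    for (k in seq_len(nrow(ot))) {
      repeat {
        d <- draw_positions(1L, spec$genome_sizes, bait_chrom, cut,
                            exclusion = 300000L, margin = 60000L)
        far <- TRUE
        if (length(placed$pos))
          far <- all(placed$chrom != d$chrom |
                       abs(placed$pos - d$pos) > 10000L)
        if (far) break
      }
      placed$chrom <- c(placed$chrom, d$chrom)
      placed$pos <- c(placed$pos, d$pos)
      m <- ot$mismatches[k]
      proto <- strsplit(spec$guide, "")[[1]]
      if (m > 0L) {
        at <- sample.int(20L, m)
        for (j in at)
          proto[j] <- sample(setdiff(DNA_ALPHABET, proto[j]), 1L)
      }
      pk <- ot$pam[k]
      pam_tail <- if (is.character(pk)) {
        switch(pk, NGG = "GG", NAG = "AG", none = "TT",
               stopf("unknown PAM type %s", pk))
      } else if (isTRUE(pk)) "GG" else "TT"
      pam_seq <- paste0(sample(DNA_ALPHABET, 1L), pam_tail)
      fwd <- paste0(paste(proto, collapse = ""), pam_seq)
      strand <- sample(c("+", "-"), 1L)
      written <- if (strand == "+") fwd else revcomp(fwd)
      s <- d$pos
      substr(genome[[d$chrom]], s, s + 22L) <- written
      sites <- rbind(sites, data.table(
        site_id = sprintf("OT%02d", k), chrom = d$chrom, start = s,
        strand = strand, cut = cut_from_site(s, strand),
        mismatches = as.integer(m), pam_ok = pam_tail %in% c("GG", "AG"),
        seq = fwd))
    }
  }
  list(genome = genome, bait = bait, offtargets = sites)
}

#' Simulate original molecules with a truth table
#'
#' Each molecule is a bait-side sequence from the primer through a
#' breakpoint drawn for its category, joined to the category-appropriate
#' partner sequence, with total length drawn from the fragment-size range
#' and a uniformly random 14-nt RMB.
#'
#' @param spec a [sim_spec()].
#' @param gen result of [make_genome()].
#' @return A list with `truth` (data.table `id`, `rmb`, `category`,
#'   `prey_chrom`, `prey_pos`, `prey_strand`, `indel_len`, `frag_len`) and
#'   `seqs` (character vector of molecule top-strand sequences starting at
#'   the primer).
#' @export
simulate_molecules <- function(spec, gen) {
  set.seed(spec$seed + 1L)
  n <- spec$n_molecules
  bait <- gen$bait
  chromseq <- gen$genome[[bait$chrom]]
  cutp <- bait$cut_pos
  bait_len <- cutp - bait$primer_start + 1L

  mix <- spec$mixture
  category <- sample(names(mix), n, replace = TRUE, prob = mix)
  # resection reassignment: a stated fraction of editing events becomes a
  # 5-50 kb deletion-consistent junction
  editing <- category != "germline"
  resect <- editing & runif(n) < spec$resection_mass
  category[resect] <- "large_deletion"

  rmb <- random_dna_set(n, 14L)
  frag <- sample(seq(spec$fragment_size[1], spec$fragment_size[2]), n,
                 replace = TRUE)
  seqs <- character(n)
  prey_chrom <- rep(NA_character_, n)
  prey_pos <- rep(NA_integer_, n)
  prey_strand <- rep(NA_character_, n)
  indel_len <- rep(NA_integer_, n)

  left <- substr(chromseq, bait$primer_start, cutp)

  idx <- which(category == "germline")
  if (length(idx))
    seqs[idx] <- substring(chromseq, bait$primer_start,
                           bait$primer_start + frag[idx] - 1L)

  idx <- which(category == "small_deletion")
  if (length(idx)) {
    d <- sample(seq(spec$del_range[1], spec$del_range[2]), length(idx),
                replace = TRUE)
    indel_len[idx] <- d
    rl <- frag[idx] - bait_len
    seqs[idx] <- paste0(left, substring(chromseq, cutp + 1L + d,
                                        cutp + d + rl))
  }

  idx <- which(category == "small_insertion")
  if (length(idx)) {
    ins_len <- sample(seq(spec$ins_range[1], spec$ins_range[2]),
                      length(idx), replace = TRUE)
    indel_len[idx] <- ins_len
    ins <- vapply(ins_len, random_dna, character(1))
    rl <- pmax(frag[idx] - bait_len - ins_len, 20L)
    seqs[idx] <- paste0(left, ins, substring(chromseq, cutp + 1L,
                                             cutp + rl))
  }

  idx <- which(category == "large_deletion")
  if (length(idx)) {
    isres <- resect[idx]
    dist <- integer(length(idx))
    dist[!isres] <- pmin(20L + as.integer(round(rexp(sum(!isres),
                                                     1 / 1200))), 5000L)
    if (any(isres))
      dist[isres] <- 5000L + pmin(as.integer(round(
        rexp(sum(isres), 1 / spec$resection_scale))), 45000L)
    pp <- cutp + dist
    prey_chrom[idx] <- bait$chrom
    prey_pos[idx] <- pp
    prey_strand[idx] <- "+"
    indel_len[idx] <- dist
    rl <- frag[idx] - bait_len
    seqs[idx] <- paste0(left, substring(chromseq, pp, pp + rl - 1L))
  }

  idx <- which(category == "inversion")
  if (length(idx)) {
    off <- sample(50:5000, length(idx), replace = TRUE) *
      sample(c(-1L, 1L), length(idx), replace = TRUE)
    pp <- cutp + off
    prey_chrom[idx] <- bait$chrom
    prey_pos[idx] <- pp
    prey_strand[idx] <- "-"
    rl <- frag[idx] - bait_len
    seqs[idx] <- paste0(left, revcomp(substring(chromseq, pp - rl + 1L,
                                                pp)))
  }

  tx <- which(category %in% c("background_translocation",
                              "offtarget_translocation"))
  if (length(tx)) {
    pch <- character(length(tx))
    ppos <- integer(length(tx))
    bg <- category[tx] == "background_translocation"
    if (any(bg)) {
      d <- draw_positions(sum(bg), spec$genome_sizes, bait$chrom, cutp)
      pch[bg] <- d$chrom
      ppos[bg] <- d$pos
    }
    if (any(!bg)) {
      if (is.null(gen$offtargets) || nrow(gen$offtargets) == 0L)
        stopf("offtarget_translocation in mixture but no implanted sites")
      k <- sample.int(nrow(gen$offtargets), sum(!bg), replace = TRUE)
      pch[!bg] <- gen$offtargets$chrom[k]
      ppos[!bg] <- gen$offtargets$cut[k] +
        as.integer(round(rnorm(sum(!bg), 0, 15)))
    }
    pstr <- sample(c("+", "-"), length(tx), replace = TRUE)
    prey_chrom[tx] <- pch
    prey_pos[tx] <- ppos
    prey_strand[tx] <- pstr
    rl <- frag[tx] - bait_len
    right <- character(length(tx))
    for (ch in unique(pch)) {
      sel <- pch == ch
      plus <- sel & pstr == "+"
      minus <- sel & pstr == "-"
      if (any(plus))
        right[plus] <- substring(gen$genome[[ch]], ppos[plus],
                                 ppos[plus] + rl[plus] - 1L)
      if (any(minus))
        right[minus] <- revcomp(substring(gen$genome[[ch]],
                                          ppos[minus] - rl[minus] + 1L,
                                          ppos[minus]))
    }
    seqs[tx] <- paste0(left, right)
  }

  truth <- data.table(id = sprintf("M%06d", seq_len(n)), rmb = rmb,
                      category = category, prey_chrom = prey_chrom,
                      prey_pos = prey_pos, prey_strand = prey_strand,
                      indel_len = indel_len, frag_len = frag)
  list(truth = truth, seqs = seqs)
}

# Apply independent per-base substitution errors to a vector of reads.
apply_errors <- function(strs, rate) {
  if (rate <= 0) return(strs)
  k <- rbinom(length(strs), nchar(strs), rate)
  for (i in which(k > 0L)) {
    s <- strsplit(strs[i], "")[[1]]
    at <- sample.int(length(s), k[i])
    for (j in at) s[j] <- sample(setdiff(DNA_ALPHABET, s[j]), 1L)
    strs[i] <- paste(s, collapse = "")
  }
  strs
}

#' PCR-amplify molecules and emit paired reads
#'
#' Each molecule is copied `1 + Poisson(duplication)` times; every copy
#' gets independent per-base substitution errors (including inside the
#' RMB). Read 1 is the primer-anchored strand, read 2 carries the bridge
#' adapter (`flank5 + RMB + flank3`) followed by the reverse complement of
#' the fragment end.
#'
#' @param molecules result of [simulate_molecules()].
#' @param spec a [sim_spec()].
#' @param adapters an [adapter_spec()]; defaults are rebuilt from the
#'   spec's read structure when omitted (requires `bait_primer`).
#' @return A list with `reads` (read pair table), `copies` (integer per
#'   molecule), and `adapters`.
#' @export
amplify_and_sequence <- function(molecules, spec, adapters) {
  set.seed(spec$seed + 2L)
  truth <- molecules$truth
  n <- nrow(truth)
  copies <- 1L + rpois(n, spec$duplication)
  idx <- rep(seq_len(n), copies)
  copy_no <- sequence(copies)

  r1 <- substr(molecules$seqs[idx], 1L, spec$read_len)
  ad_len <- nchar(adapters$bridge_flank5) + 14L +
    nchar(adapters$bridge_flank3)
  gen_len <- spec$read_len - ad_len
  frag_end <- revcomp(substring(molecules$seqs[idx],
                                nchar(molecules$seqs[idx]) - gen_len + 1L))
  r2 <- paste0(adapters$bridge_flank5, truth$rmb[idx],
               adapters$bridge_flank3, frag_end)

  r1 <- apply_errors(r1, spec$error_rate)
  r2 <- apply_errors(r2, spec$error_rate)
  reads <- data.table(id = sprintf("%s.%d", truth$id[idx], copy_no),
                      seq1 = r1, qual1 = strrep("I", nchar(r1)),
                      seq2 = r2, qual2 = strrep("I", nchar(r2)))
  list(reads = reads, copies = copies, adapters = adapters)
}

#' Simulate a complete PEM-seq library
#'
#' Convenience wrapper: builds the genome, simulates molecules, amplifies
#' and sequences them, and assembles the matching adapter spec (the bait
#' primer is read off the genome).
#'
#' @param spec a [sim_spec()].
#' @param gen optional pre-built [make_genome()] result, so treated and
#'   control libraries can share one genome.
#' @return A list with `genome`, `bait`, `offtargets`, `truth` (including
#'   a `copies` column), `reads`, `adapters`, and `spec`.
#' @export
simulate_library <- function(spec, gen = NULL) {
  if (is.null(gen)) gen <- make_genome(spec)
  mol <- simulate_molecules(spec, gen)
  primer <- substr(gen$genome[[gen$bait$chrom]], gen$bait$primer_start,
                   gen$bait$primer_end)
  adapters <- adapter_spec(bait_primer = primer)
  amp <- amplify_and_sequence(mol, spec, adapters)
  truth <- copy(mol$truth)
  truth[, copies := amp$copies]
  list(genome = gen$genome, bait = gen$bait, offtargets = gen$offtargets,
       truth = truth, reads = amp$reads, adapters = adapters, spec = spec)
}

#' Simulate deduplicated junction sets for hotspot calling
#'
#' Generates per-replicate genome-wide translocation junction tables:
#' implanted off-target sites receive junctions scattered tightly around
#' their presumed cut (normal, sd `scatter_sd`, balanced orientations),
#' and a uniform background is spread over the genome outside the bait
#' exclusion zone.
#'
#' @param gen result of [make_genome()].
#' @param site_counts integer matrix (`n_sites` x `n_replicates`) or
#'   vector (recycled across replicates) of junction counts per site.
#' @param n_background background junctions per replicate.
#' @param n_replicates number of replicate libraries.
#' @param scatter_sd sd (bp) of junction scatter around each cut.
#' @param seed RNG seed.
#' @return A list of `n_replicates` data.tables (`chrom`, `pos`,
#'   `strand`).
#' @export
simulate_junction_set <- function(gen, site_counts, n_background = 167L,
                                  n_replicates = 3L, scatter_sd = 15,
                                  seed = 1L) {
  set.seed(seed)
  sites <- gen$offtargets
  if (is.vector(site_counts))
    site_counts <- matrix(site_counts, nrow = length(site_counts),
                          ncol = n_replicates)
  stopifnot(nrow(site_counts) == nrow(sites))
  bait <- gen$bait
  sizes <- vapply(gen$genome, nchar, integer(1))
  lapply(seq_len(n_replicates), function(r) {
    parts <- list()
    for (k in seq_len(nrow(sites))) {
      nk <- site_counts[k, r]
      if (nk > 0L)
        parts[[length(parts) + 1L]] <- data.table(
          chrom = sites$chrom[k],
          pos = sites$cut[k] + as.integer(round(rnorm(nk, 0, scatter_sd))),
          strand = sample(c("+", "-"), nk, replace = TRUE))
    }
    if (n_background > 0L) {
      d <- draw_positions(n_background, sizes, bait$chrom, bait$cut_pos)
      parts[[length(parts) + 1L]] <- data.table(
        chrom = d$chrom, pos = d$pos,
        strand = sample(c("+", "-"), n_background, replace = TRUE))
    }
    out <- rbindlist(parts)
    setorder(out, chrom, pos, strand)
    out
  })
}

#' Write a toy genome as FASTA
#' @param genome named character vector of chromosome sequences.
#' @param path output FASTA path.
#' @export
write_genome_fasta <- function(genome, path) {
  x <- Biostrings::DNAStringSet(genome)
  Biostrings::writeXStringSet(x, path)
  invisible(NULL)
}

#' Read a genome FASTA into the named character form used internally
#' @param path FASTA path.
#' @return Named character vector of chromosome sequences.
#' @export
read_genome_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), sub(" .*", "", names(x)))
}
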
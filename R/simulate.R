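# Synthetic Ig-seq data with the MAF read structure.
#
# Molecules are drawn from a spike-in pool and/or a simulated B-cell
# repertoire, tagged with a reverse UID (RID) at reverse transcription,
# amplified through per-FID PCR lineages with per-primer efficiency bias
# and per-cycle substitution errors, and sequenced with i.i.d. substitution
# errors. Emitted reads are FID | insert | revcomp(RID).

#' Simulator parameters
#'
#' @param rid_length reverse-UID length in nt (default 12; theoretical
#'   diversity 4^12 ~ 1.7e7)
#' @param fid_length forward-UID length in nt (default 10; ~1.05e6)
#' @param n_transcripts molecules reverse-transcribed per replicate library
#' @param pcr_cycles first-PCR cycle count (default 20)
#' @param pcr_error_rate substitutions per base per replication
#' @param seq_error_rate substitutions per base per read
#' @param efficiency named per-cycle amplification probability in (0,1] by
#'   V gene (allele-stripped); NULL = uniform 1
#' @param reads_per_molecule_mean mean sequencing depth per molecule
#' @param min_reads_per_molecule lower truncation of the per-molecule read
#'   count (default 1). Set to 0 to model a finite sequencing budget, in
#'   which case weakly amplified molecules can drop out.
#' @param fid_mult_rate scale of FID multiplicity: a molecule of a gene with
#'   efficiency e carries 1 + Poisson(fid_mult_rate * e) distinct FIDs
#' @param spikein_fraction fraction of molecules drawn from the spike-in
#'   pool when a repertoire is also present (default 12500/147500, the
#'   spike-to-cDNA ratio used at library scale)
#' @param paired emit paired reads split with a fixed overlap
#' @param paired_overlap overlap length in paired mode
#' @param seed RNG seed; all simulator randomness derives from it
#' @return object of class `sim_params`
#' @export
simulator_params <- function(rid_length = 12L, fid_length = 10L,
                             n_transcripts = 1000L, pcr_cycles = 20L,
                             pcr_error_rate = 0, seq_error_rate = 0,
                             efficiency = NULL,
                             reads_per_molecule_mean = 10,
                             min_reads_per_molecule = 1L,
                             fid_mult_rate = 4,
                             spikein_fraction = 12500 / 147500,
                             paired = FALSE, paired_overlap = 30L,
                             seed = 1L) {
  if (rid_length < 6 || fid_length < 6) {
    stop_maf("UID lengths must be >= 6 nt", "mafseq_validation_error")
  }
  for (r in c(pcr_error_rate, seq_error_rate)) {
    if (r < 0 || r >= 0.5) stop_maf("error rates must be in [0, 0.5)",
                                    "mafseq_validation_error")
  }
  if (n_transcripts < 1) stop_maf("n_transcripts must be >= 1",
                                  "mafseq_validation_error")
  if (!is.null(efficiency) &&
      (any(efficiency <= 0) || any(efficiency > 1))) {
    stop_maf("efficiencies must lie in (0, 1]", "mafseq_validation_error")
  }
  structure(list(rid_length = as.integer(rid_length),
                 fid_length = as.integer(fid_length),
                 n_transcripts = as.integer(n_transcripts),
                 pcr_cycles = as.integer(pcr_cycles),
                 pcr_error_rate = pcr_error_rate,
                 seq_error_rate = seq_error_rate,
                 efficiency = efficiency,
                 reads_per_molecule_mean = reads_per_molecule_mean,
                 min_reads_per_molecule = as.integer(min_reads_per_molecule),
                 fid_mult_rate = fid_mult_rate,
                 spikein_fraction = spikein_fraction,
                 paired = paired, paired_overlap = as.integer(paired_overlap),
                 seed = as.integer(seed)),
            class = "sim_params")
}

#' Repertoire simulation parameters
#'
#' Defaults follow the biology of the two sorted subsets: naive clones are
#' near-germline singletons (Poisson SHM mean 0.2) confined to one cellular
#' replicate; memory clonotypes are expanded, heavily mutated (Poisson SHM
#' mean 22 per nt variant) and spread across replicates, with IgG subclass
#' weights 5:3:1:0 for IgG1:IgG2:IgG3:IgG4.
#'
#' @param subset "naive" or "memory"
#' @param n_clones number of clonotypes
#' @param clone_size_meanlog,clone_size_sdlog lognormal cell-count
#'   distribution for memory clones
#' @param shm_per_variant Poisson mean of substitutions per nt variant
#' @param variants_lambda extra nt variants per clonotype ~ Poisson
#' @param cdr3_mutation_prob probability that a non-founder variant carries
#'   one CDR3 codon substitution (intraclonal CDR3 diversity)
#' @param subclass_weights named weights over constant-region subclasses
#' @param n_replicates cellular replicates the repertoire is split into
#' @param detection_prob if set, replicate membership is homogeneous
#'   Bernoulli(p) per clone per replicate (one cell per hit) instead of
#'   multinomial cell splitting
#' @param seed RNG seed
#' @return object of class `rep_params`
#' @export
repertoire_params <- function(subset = c("naive", "memory"), n_clones = 100L,
                              clone_size_meanlog = 1.5, clone_size_sdlog = 1,
                              shm_per_variant = NULL, variants_lambda = NULL,
                              cdr3_mutation_prob = 0.1,
                              subclass_weights = NULL, n_replicates = 2L,
                              detection_prob = NULL, seed = 1L) {
  subset <- match.arg(subset)
  if (is.null(shm_per_variant)) {
    shm_per_variant <- if (subset == "naive") 0.2 else 22
  }
  if (is.null(variants_lambda)) {
    variants_lambda <- if (subset == "naive") 0 else 2
  }
  if (is.null(subclass_weights)) {
    subclass_weights <- if (subset == "naive") c(IgM = 1) else
      c(IgG1 = 5, IgG2 = 3, IgG3 = 1, IgG4 = 0)
  }
  if (any(subclass_weights < 0) || sum(subclass_weights) <= 0) {
    stop_maf("subclass weights must be non-negative, not all zero",
             "mafseq_validation_error")
  }
  if (n_replicates < 1) stop_maf("n_replicates must be >= 1",
                                 "mafseq_validation_error")
  structure(list(subset = subset, n_clones = as.integer(n_clones),
                 clone_size_meanlog = clone_size_meanlog,
                 clone_size_sdlog = clone_size_sdlog,
                 shm_per_variant = shm_per_variant,
                 variants_lambda = variants_lambda,
                 cdr3_mutation_prob = cdr3_mutation_prob,
                 subclass_weights = subclass_weights,
                 n_replicates = as.integer(n_replicates),
                 detection_prob = detection_prob, seed = as.integer(seed)),
            class = "rep_params")
}

# insert assembly for a biological rearrangement (no spike-in elements)
assemble_bio_insert <- function(layout, v_seq, v_anchor, j_seq, j_anchor,
                                cdr3_nt, c_prefix) {
  paste0(layout$leader, substr(v_seq, 1, v_anchor), cdr3_nt,
         substr(j_seq, j_anchor + 4L, nchar(j_seq)), c_prefix)
}

# 1-based insert positions where SHM may land: V body outside the primer
# footprint, and J after the Trp codon; never the junction or anchors.
shm_allowed_positions <- function(layout, v_anchor, cdr3_len, j_len, j_anchor) {
  lead <- nchar(layout$leader)
  v_span <- if (v_anchor > layout$primer_footprint) {
    seq(lead + layout$primer_footprint + 1L, lead + v_anchor)
  } else integer(0)
  j_start <- lead + v_anchor + cdr3_len
  j_tail <- j_len - (j_anchor + 3L)
  j_span <- if (j_tail > 0) seq(j_start + 1L, j_start + j_tail) else integer(0)
  c(v_span, j_span)
}

#' Simulate a B-cell repertoire as clonotype lineages
#'
#' @param db a `germline_db`
#' @param params a `rep_params`
#' @param layout a `maf_layout` (leader / constant prefixes / footprint)
#' @param cdr3_length_range CDR3 amino-acid length interval
#' @return object of class `sim_repertoire`: list with `clones`,
#'   `variants` (one row per distinct nt variant, with assembled insert,
#'   planted SHM count and subclass) and `occupancy` (variant_id,
#'   replicate_id, cells)
#' @export
generate_repertoire <- function(db, params, layout = default_layout(db),
                                cdr3_length_range = c(10, 20)) {
  if (is.null(db$v) || nrow(db$v) == 0 || nrow(db$j) == 0) {
    stop_maf("empty germline database", "mafseq_validation_error")
  }
  with_seed(params$seed, {
    n <- params$n_clones
    v_idx <- sample(nrow(db$v), n, replace = TRUE)
    j_idx <- sample(nrow(db$j), n, replace = TRUE)
    sizes <- if (params$subset == "naive") rep(1L, n) else
      pmax(1L, round(rlnorm(n, params$clone_size_meanlog,
                            params$clone_size_sdlog)))
    nvar <- if (params$subset == "naive") rep(1L, n) else
      1L + rpois(n, params$variants_lambda)
    w <- params$subclass_weights
    clone_rows <- vector("list", n)
    var_rows <- list()
    occ_rows <- list()
    vid <- 0L
    for (i in seq_len(n)) {
      v <- db$v[v_idx[i], ]; j <- db$j[j_idx[i], ]
      v_cys <- substr(v$sequence, v$anchor_offset + 1, v$anchor_offset + 3)
      la <- sample(seq(cdr3_length_range[1], cdr3_length_range[2]), 1)
      cdr3 <- paste0(v_cys, random_sense_codons(la - 2), "TGG")
      clone_rows[[i]] <- data.frame(
        clone_id = sprintf("C%05d", i), v_name = v$name, j_name = j$name,
        cdr3_nt = cdr3, cdr3_aa = translate_nt(cdr3), size = sizes[i],
        n_variants = nvar[i], stringsAsFactors = FALSE)
      allowed <- shm_allowed_positions(layout, v$anchor_offset, nchar(cdr3),
                                       nchar(j$sequence), j$anchor_offset)
      for (k in seq_len(nvar[i])) {
        vid <- vid + 1L
        cdr3_k <- cdr3
        if (k > 1 && runif(1) < params$cdr3_mutation_prob && la > 4) {
          at <- sample(2:(la - 1), 1)  # spare the anchors
          cdr3_k <- paste0(substr(cdr3, 1, 3 * (at - 1)),
                           sample(SENSE_CODONS, 1),
                           substr(cdr3, 3 * at + 1, nchar(cdr3)))
        }
        subcl <- sample(names(w), 1, prob = w)
        cseq <- db$c$sequence[match(subcl, db$c$subclass_label)]
        ins <- assemble_bio_insert(layout, v$sequence, v$anchor_offset,
                                   j$sequence, j$anchor_offset, cdr3_k, cseq)
        n_shm <- rpois(1, params$shm_per_variant)
        pos <- sample(allowed, min(n_shm, length(allowed)))
        if (length(pos)) ins <- substitute_bases(ins, pos)
        var_rows[[vid]] <- data.frame(
          variant_id = sprintf("C%05d.v%02d", i, k),
          clone_id = sprintf("C%05d", i), v_name = v$name, j_name = j$name,
          cdr3_nt = cdr3_k, cdr3_aa = translate_nt(cdr3_k),
          n_shm = length(pos), subclass = subcl, insert = ins,
          stringsAsFactors = FALSE)
        # replicate occupancy
        if (!is.null(params$detection_prob)) {
          hit <- which(runif(params$n_replicates) < params$detection_prob)
          if (length(hit)) {
            occ_rows[[length(occ_rows) + 1]] <- data.frame(
              variant_id = var_rows[[vid]]$variant_id, replicate_id = hit,
              cells = 1L, stringsAsFactors = FALSE)
          }
        } else if (params$subset == "naive") {
          occ_rows[[length(occ_rows) + 1]] <- data.frame(
            variant_id = var_rows[[vid]]$variant_id,
            replicate_id = sample(params$n_replicates, 1), cells = 1L,
            stringsAsFactors = FALSE)
        } else {
          cells_k <- max(1L, round(sizes[i] / nvar[i]))
          split <- as.vector(stats::rmultinom(1, cells_k,
                                              rep(1, params$n_replicates)))
          hit <- which(split > 0)
          occ_rows[[length(occ_rows) + 1]] <- data.frame(
            variant_id = var_rows[[vid]]$variant_id, replicate_id = hit,
            cells = split[hit], stringsAsFactors = FALSE)
        }
      }
    }
    structure(list(clones = do.call(rbind, clone_rows),
                   variants = do.call(rbind, var_rows),
                   occupancy = do.call(rbind, occ_rows),
                   n_replicates = params$n_replicates),
              class = "sim_repertoire")
  })
}

#' Reverse-transcribe a pool into RID-tagged molecules
#'
#' Draws `n_transcripts` molecules per replicate library, multinomially by
#' relative concentration (spike-ins) and/or per-replicate cell counts
#' (repertoire variants), and attaches an independent uniform random RID to
#' each. RID collisions within a library are counted in the
#' `rid_collisions` attribute; a warning is raised when the expected
#' collision load n^2/4^rid_length exceeds 1e-3.
#'
#' @param params a `sim_params`
#' @param spikeins optional `spikein_set`
#' @param repertoire optional `sim_repertoire`
#' @param manifest named concentrations for the spike-in pool (defaults to
#'   the set's own); must sum to 1
#' @return data.frame of molecules (class `true_molecules`): molecule_id,
#'   source_type, source_id, replicate_id, v_name, j_name, cdr3_aa,
#'   subclass, insert, rid
#' @export
transcribe_and_tag <- function(params, spikeins = NULL, repertoire = NULL,
                               manifest = NULL) {
  if (is.null(spikeins) && is.null(repertoire)) {
    stop_maf("need a spike-in set and/or a repertoire", "mafseq_validation_error")
  }
  if (!is.null(spikeins) && is.null(manifest)) {
    manifest <- setNames(spikeins$standards$relative_concentration,
                         spikeins$standards$standard_id)
  }
  if (!is.null(manifest) && abs(sum(manifest) - 1) > 1e-6) {
    stop_maf("manifest concentrations must sum to 1", "mafseq_validation_error")
  }
  n_rep <- if (!is.null(repertoire)) repertoire$n_replicates else 1L
  with_seed(params$seed, {
    # candidate sources with per-replicate weights
    src <- list()
    if (!is.null(spikeins)) {
      st <- spikeins$standards
      sf <- if (is.null(repertoire)) 1 else params$spikein_fraction
      for (r in seq_len(n_rep)) {
        src[[length(src) + 1]] <- data.frame(
          source_type = "spikein", source_id = st$standard_id,
          replicate_id = r, v_name = st$v_name, j_name = st$j_name,
          cdr3_aa = st$cdr3_aa, subclass = st$subclass,
          insert = st$full_sequence,
          weight = sf * unname(manifest[st$standard_id]),
          stringsAsFactors = FALSE)
      }
    }
    if (!is.null(repertoire)) {
      occ <- merge(repertoire$occupancy, repertoire$variants,
                   by = "variant_id")
      bf <- if (is.null(spikeins)) 1 else 1 - params$spikein_fraction
      for (r in seq_len(n_rep)) {
        o <- occ[occ$replicate_id == r, ]
        if (nrow(o) == 0) next
        src[[length(src) + 1]] <- data.frame(
          source_type = "repertoire", source_id = o$variant_id,
          replicate_id = r, v_name = o$v_name, j_name = o$j_name,
          cdr3_aa = o$cdr3_aa, subclass = o$subclass, insert = o$insert,
          weight = bf * o$cells / sum(o$cells), stringsAsFactors = FALSE)
      }
    }
    pool <- do.call(rbind, src)
    mols <- list()
    collisions <- 0L
    for (r in unique(pool$replicate_id)) {
      p <- pool[pool$replicate_id == r, ]
      counts <- as.vector(stats::rmultinom(1, params$n_transcripts, p$weight))
      idx <- rep(seq_len(nrow(p)), counts)
      m <- p[idx, c("source_type", "source_id", "replicate_id", "v_name",
                    "j_name", "cdr3_aa", "subclass", "insert")]
      m$rid <- random_nt(nrow(m), params$rid_length)
      collisions <- collisions + sum(duplicated(m$rid))
      mols[[length(mols) + 1]] <- m
    }
    out <- do.call(rbind, mols)
    out$molecule_id <- sprintf("M%07d", seq_len(nrow(out)))
    rownames(out) <- NULL
    out <- out[, c("molecule_id", "source_type", "source_id", "replicate_id",
                   "v_name", "j_name", "cdr3_aa", "subclass", "insert", "rid")]
    if (params$n_transcripts^2 / 4^params$rid_length > 1e-3) {
      warning(sprintf("expected RID collision load %.3g; observed %d collisions",
                      params$n_transcripts^2 / 4^params$rid_length, collisions))
    }
    attr(out, "rid_collisions") <- collisions
    class(out) <- c("true_molecules", "data.frame")
    out
  })
}

draw_read_counts <- function(lambda, min_reads) {
  n <- length(lambda)
  k <- rpois(n, lambda)
  if (min_reads > 0) {
    low <- which(k < min_reads)
    guard <- 0L
    while (length(low) && guard < 1000L) {
      k[low] <- rpois(length(low), lambda[low])
      low <- low[k[low] < min_reads]
      guard <- guard + 1L
    }
    k[k < min_reads] <- min_reads  # pathological lambda ~ 0
  }
  k
}

#' Amplify molecules and emit sequenced reads
#'
#' Per molecule: the number of distinct FIDs is 1 + Poisson(fid_mult_rate *
#' efficiency), relative post-PCR abundance is (1 + efficiency)^cycles
#' (normalized to mean 1 across the pool) and the read count is Poisson
#' with that relative mean, truncated at `min_reads_per_molecule`. PCR
#' substitution errors follow per-FID amplification lineages (errors in an
#' early replication are shared by the descendants sampled from it);
#' sequencing errors are i.i.d. per base over the whole read, flagged at
#' Phred 15 versus a constant Phred 37 elsewhere.
#'
#' @param molecules a `true_molecules` data.frame
#' @param params a `sim_params`
#' @param out_prefix if non-NULL, writes `<prefix>.fastq` (or `_R1/_R2` in
#'   paired mode) and `<prefix>_truth.tsv`
#' @return list of class `sim_reads`: `reads` (read_id, sequence, quality,
#'   replicate_id), `truth` (read-level ground truth incl. molecule_id and
#'   true insert), `fids` (molecule_id, fid)
#' @export
amplify_and_sequence <- function(molecules, params, out_prefix = NULL) {
  if (nrow(molecules) == 0) stop_maf("no molecules", "mafseq_validation_error")
  genes <- gene_of(molecules$v_name)
  eff <- rep(1, nrow(molecules))
  if (!is.null(params$efficiency)) {
    unknown <- setdiff(names(params$efficiency), unique(genes))
    if (length(unknown)) {
      stop_maf(paste0("efficiency map names unknown V gene(s): ",
                      paste(unknown, collapse = ", ")),
               "mafseq_validation_error")
    }
    missing <- setdiff(unique(genes), names(params$efficiency))
    if (length(missing)) {
      stop_maf(paste0("efficiency missing for V gene(s): ",
                      paste(missing, collapse = ", ")),
               "mafseq_validation_error")
    }
    eff <- unname(params$efficiency[genes])
  }
  with_seed(params$seed + 1L, {
    rel_amp <- (1 + eff)^params$pcr_cycles
    w <- rel_amp / mean(rel_amp)
    n_reads <- draw_read_counts(params$reads_per_molecule_mean * w,
                                params$min_reads_per_molecule)
    keep <- which(n_reads > 0)
    n_fids <- 1L + rpois(nrow(molecules), params$fid_mult_rate * eff)
    # FID pools per molecule; global lineage ids for the PCR error model
    fid_of_mol <- lapply(n_fids, function(k) random_nt(k, params$fid_length))
    fid_base <- cumsum(c(0L, n_fids))
    mol_idx <- rep(keep, n_reads[keep])
    fid_pick <- unlist(lapply(keep, function(i)
      sample.int(n_fids[i], n_reads[i], replace = TRUE)), use.names = FALSE)
    lineage <- fid_base[mol_idx] + fid_pick
    fids <- unlist(lapply(seq_along(mol_idx), function(r)
      fid_of_mol[[mol_idx[r]]][fid_pick[r]]), use.names = FALSE)
    ins_len <- nchar(molecules$insert)[mol_idx]
    pcr <- cpp_pcr_errors(as.integer(lineage), as.integer(ins_len),
                          params$pcr_cycles, params$pcr_error_rate)
    inserts <- cpp_apply_muts(molecules$insert[mol_idx], pcr$pos, pcr$delta)
    seqs <- paste0(fids, inserts, revcomp(molecules$rid[mol_idx]))
    # sequencing errors over the whole read, Q15 at error positions
    len <- nchar(seqs)
    quals <- vapply(len, function(L) strrep("F", L), "")
    nerr <- rbinom(length(seqs), len, params$seq_error_rate)
    hit <- which(nerr > 0)
    if (length(hit)) {
      pos_list <- vector("list", length(seqs))
      delta_list <- vector("list", length(seqs))
      pos_list[] <- list(integer(0))
      delta_list[] <- list(integer(0))
      for (r in hit) {
        p <- sample.int(len[r], nerr[r]) - 1L
        pos_list[[r]] <- p
        delta_list[[r]] <- sample.int(3L, nerr[r], replace = TRUE)
        q <- strsplit(quals[r], "")[[1]]
        q[p + 1L] <- "0"  # Phred 15
        quals[r] <- paste(q, collapse = "")
      }
      seqs <- cpp_apply_muts(seqs, pos_list, delta_list)
    }
    read_id <- sprintf("R%08d", seq_along(seqs))
    reads <- data.frame(read_id = read_id, sequence = seqs, quality = quals,
                        replicate_id = molecules$replicate_id[mol_idx],
                        stringsAsFactors = FALSE)
    truth <- data.frame(read_id = read_id,
                        molecule_id = molecules$molecule_id[mol_idx],
                        source = molecules$source_id[mol_idx],
                        replicate_id = molecules$replicate_id[mol_idx],
                        v_name = molecules$v_name[mol_idx],
                        j_name = molecules$j_name[mol_idx],
                        cdr3_aa = molecules$cdr3_aa[mol_idx],
                        fid = fids, rid = molecules$rid[mol_idx],
                        true_sequence = molecules$insert[mol_idx],
                        stringsAsFactors = FALSE)
    fid_table <- data.frame(
      molecule_id = rep(molecules$molecule_id, n_fids),
      fid = unlist(fid_of_mol, use.names = FALSE), stringsAsFactors = FALSE)
    out <- structure(list(reads = reads, truth = truth, fids = fid_table),
                     class = "sim_reads")
    if (!is.null(out_prefix)) write_sim_reads(out, params, out_prefix)
    out
  })
}

#' @export
print.sim_reads <- function(x, ...) {
  cat("sim_reads:", nrow(x$reads), "reads from",
      length(unique(x$truth$molecule_id)), "molecules\n")
  invisible(x)
}

#' Write simulated reads as FASTQ plus a ground-truth TSV
#' @param sim a `sim_reads` object
#' @param params the `sim_params` used (for paired-mode layout)
#' @param prefix output path prefix
#' @export
write_sim_reads <- function(sim, params, prefix) {
  truth_cols <- c("read_id", "molecule_id", "source", "replicate_id",
                  "v_name", "j_name", "cdr3_aa")
  write.table(sim$truth[, truth_cols], paste0(prefix, "_truth.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  if (!params$paired) {
    write_fastq(sim$reads, paste0(prefix, ".fastq"))
  } else {
    ov <- params$paired_overlap
    len <- nchar(sim$reads$sequence)
    cut <- ceiling((len + ov) / 2)
    r1 <- data.frame(read_id = sim$reads$read_id,
                     sequence = substr(sim$reads$sequence, 1, cut),
                     quality = substr(sim$reads$quality, 1, cut),
                     stringsAsFactors = FALSE)
    r2s <- substr(sim$reads$sequence, cut - ov + 1, len)
    r2q <- substr(sim$reads$quality, cut - ov + 1, len)
    r2 <- data.frame(read_id = sim$reads$read_id,
                     sequence = revcomp(r2s),
                     quality = vapply(strsplit(r2q, ""), function(x)
                       paste(rev(x), collapse = ""), ""),
                     stringsAsFactors = FALSE)
    write_fastq(r1, paste0(prefix, "_R1.fastq"))
    write_fastq(r2, paste0(prefix, "_R2.fastq"))
  }
  invisible(prefix)
}
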
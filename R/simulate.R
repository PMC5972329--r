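# Truth-tagged synthetic TCR-alpha repertoires. The generator emulates the
# data-generating process the analysis assumes: VJ-recombined clones with
# frame-preserving junctional variation, per-site independent point
# mutations with nucleotide / transition / motif bias, occasional
# frameshift indels, and (optionally) a heterozygous individual carrying
# two constant-region allotypes at ~50/50.

#' Simulation configuration
#'
#' Defaults mirror the restricted-PCR study conditions: 48 clones, a
#' mutation rate of 4.5 per 1,000 bp, a transition fraction of 0.53, two
#' frameshift clones expected per 48, a 25-segment J library and uniform
#' base composition.
#'
#' @param seed Integer seed; all randomness in the simulator flows from it.
#' @param n_clones Number of clones to generate.
#' @param v_length,c_length V and C reference lengths in nt (multiples of
#'   3; `v_length = 0` drops the V/J part and simulates a constant-region
#'   pool).
#' @param j_length J segment length in nt.
#' @param j_library_size Number of J segments.
#' @param composition Named base weights for reference generation.
#' @param junction_indel_range Maximum nt trimmed from each side of the
#'   VJ junction; net junction length change is kept a multiple of 3
#'   (expressed CDR3 length variation is in-frame), so out-of-frame clones
#'   arise only through `indel_rate`.
#' @param mutation_rate Substitution hazard per bp.
#' @param base_bias Named per-nucleotide rate multipliers.
#' @param transition_prob Probability a substitution is a transition
#'   (otherwise uniform over the two transversions).
#' @param motif_multipliers Named rate multipliers applied at motif-mutable
#'   positions (classes AID_RGYW, AID_WRCY, WA, TW); at positions mutable
#'   for several classes the largest multiplier applies.
#' @param indel_rate Expected frameshift (1-nt deletion) events per clone.
#' @param heterozygous Simulate two constant-region allotypes?
#' @param n_diagnostic Diagnostic substitutions distinguishing allotype B
#'   from A.
#' @param allele_ratio Expected fraction of clones drawn from allele A.
#' @return List of class `shm_sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_clones = 48L,
                       v_length = 291L,
                       c_length = 336L,
                       j_length = 57L,
                       j_library_size = 25L,
                       composition = c(A = 1, C = 1, G = 1, T = 1),
                       junction_indel_range = 3L,
                       mutation_rate = 4.5e-3,
                       base_bias = c(A = 1, C = 1, G = 1, T = 1),
                       transition_prob = 0.53,
                       motif_multipliers = c(AID_RGYW = 1, AID_WRCY = 1,
                                             WA = 1, TW = 1),
                       indel_rate = 2 / 48,
                       heterozygous = FALSE,
                       n_diagnostic = 3L,
                       allele_ratio = 0.5) {
  if (mutation_rate < 0 || indel_rate < 0) stop_shm("rates must be >= 0")
  if (transition_prob < 0 || transition_prob > 1) {
    stop_shm("transition_prob must lie in [0, 1]")
  }
  if (allele_ratio <= 0 || allele_ratio >= 1) {
    stop_shm("allele_ratio must lie in (0, 1)")
  }
  if (all(composition == 0)) stop_shm("composition weights all zero")
  if (any(base_bias < 0) || any(motif_multipliers < 0)) {
    stop_shm("bias multipliers must be >= 0")
  }
  structure(list(
    seed = as.integer(seed), n_clones = as.integer(n_clones),
    v_length = as.integer(v_length), c_length = as.integer(c_length),
    j_length = as.integer(j_length),
    j_library_size = as.integer(j_library_size),
    composition = composition,
    junction_indel_range = as.integer(junction_indel_range),
    mutation_rate = mutation_rate, base_bias = base_bias,
    transition_prob = transition_prob,
    motif_multipliers = motif_multipliers,
    indel_rate = indel_rate, heterozygous = isTRUE(heterozygous),
    n_diagnostic = as.integer(n_diagnostic),
    allele_ratio = allele_ratio
  ), class = "shm_sim_config")
}

# random stop-free in-frame coding sequence of length n (multiple of 3)
random_coding_seq <- function(n, composition) {
  stopifnot(n %% 3 == 0)
  p <- composition[DNA_BASES] / sum(composition[DNA_BASES])
  if (n == 0) return("")
  out <- character(n / 3)
  code <- Biostrings::GENETIC_CODE
  i <- 1L
  while (i <= length(out)) {
    codon <- paste(sample(DNA_BASES, 3, replace = TRUE, prob = p),
                   collapse = "")
    if (code[[codon]] != "*") { out[i] <- codon; i <- i + 1L }
  }
  paste(out, collapse = "")
}

#' Build the germline reference set for a simulation
#'
#' Seeds the generator from `config$seed`, builds a stop-free V gene, a J
#' library, the constant region (two allotypes when heterozygous, allotype
#' B being allotype A with `n_diagnostic` replacement substitutions at
#' fixed positions) and a region map over the untrimmed V-J-C layout.
#'
#' @param config [sim_config()] object.
#' @return List: `v`, `j_library` (tibble `j_id`, `sequence`), `c_a`,
#'   `c_b` (NULL if homozygous), `diagnostic_positions` (0-based, in
#'   C-local coordinates), `region_map`.
#' @export
make_reference <- function(config) {
  stopifnot(inherits(config, "shm_sim_config"))
  set.seed(config$seed)
  if (sum(config$composition > 0) == 1) {
    warning("degenerate single-base composition", call. = FALSE)
  }
  v <- random_coding_seq(config$v_length, config$composition)
  jl <- if (config$v_length > 0) {
    tibble::tibble(
      j_id = sprintf("J%02d", seq_len(config$j_library_size)),
      sequence = vapply(seq_len(config$j_library_size), function(i) {
        random_coding_seq(config$j_length - config$j_length %% 3,
                          config$composition)
      }, character(1))
    )
  } else {
    tibble::tibble(j_id = character(0), sequence = character(0))
  }
  c_a <- random_coding_seq(config$c_length, config$composition)
  c_b <- NULL
  diag_pos <- integer(0)
  if (config$heterozygous) {
    # evenly spaced first-codon-position diagnostics => replacement changes
    diag_pos <- as.integer(seq(12, config$c_length - 12,
                               length.out = config$n_diagnostic) %/% 3) * 3L
    cb <- seq_chars(c_a)
    for (p in diag_pos) {
      for (b in sample(DNA_BASES)) {
        if (b == cb[p + 1L]) next
        cand <- cb; cand[p + 1L] <- b
        codon <- paste(cand[(p + 1L):(p + 3L)], collapse = "")
        aa <- Biostrings::GENETIC_CODE[[codon]]
        ref_aa <- Biostrings::GENETIC_CODE[[paste(cb[(p + 1L):(p + 3L)],
                                                  collapse = "")]]
        if (aa != "*" && aa != ref_aa) { cb <- cand; break }
      }
    }
    c_b <- paste(cb, collapse = "")
  }
  vl <- config$v_length
  jlen <- if (nrow(jl)) nchar(jl$sequence[1]) else 0L
  cl <- config$c_length
  # constant-region subparts in proportion (Ig domain, connecting peptide,
  # transmembrane, cytoplasmic), codon-aligned
  cb <- as.integer(round(cl * c(0.66, 0.80, 0.95) / 3) * 3)
  regions <- if (vl > 0) {
    fr3_end <- vl - 9L
    tibble::tibble(
      name = c("FR1", "CDR1", "FR2", "CDR2", "FR3", "CDR3", "FR4",
               "C-Ig", "C-CP", "C-TM", "C-CYT"),
      start = c(0L, 75L, 96L, 144L, 168L, fr3_end, vl + 18L,
                vl + jlen, vl + jlen + cb[1], vl + jlen + cb[2],
                vl + jlen + cb[3]),
      end = c(75L, 96L, 144L, 168L, fr3_end, vl + 18L, vl + jlen,
              vl + jlen + cb[1], vl + jlen + cb[2], vl + jlen + cb[3],
              vl + jlen + cl)
    )
  } else {
    tibble::tibble(
      name = c("C-Ig", "C-CP", "C-TM", "C-CYT"),
      start = c(0L, cb[1], cb[2], cb[3]),
      end = c(cb[1], cb[2], cb[3], cl)
    )
  }
  list(v = v, j_library = jl, c_a = c_a, c_b = c_b,
       diagnostic_positions = diag_pos,
       region_map = region_map(regions, frame_offset = 0L))
}

# motif-multiplier vector (one entry per template position)
motif_multiplier_vector <- function(template, multipliers) {
  mult <- rep(1, nchar(template))
  if (all(multipliers == 1)) return(mult)
  hits <- scan_motifs(template, names(multipliers))
  for (i in seq_len(nrow(hits))) {
    p <- hits$mutable_position[i] + 1L
    mult[p] <- max(mult[p], multipliers[[hits$motif_class[i]]])
  }
  mult
}

TRANSITION_OF <- c(A = "G", G = "A", C = "T", T = "C")
TRANSVERSIONS_OF <- list(A = c("C", "T"), G = c("C", "T"),
                         C = c("A", "G"), T = c("A", "G"))

#' Simulate a clone repertoire with planted truth
#'
#' Per clone: draw an allele (heterozygous configs), a J segment, and
#' frame-preserving junction trimming/addition; then mutate every site
#' independently with hazard `mutation_rate x base_bias(base) x
#' motif_multiplier(site)`, each substitution being a transition with
#' probability `transition_prob`; finally plant `rpois(indel_rate)` 1-nt
#' deletions. Every planted event is recorded in template coordinates.
#'
#' @param config [sim_config()] object.
#' @param reference Optional pre-built [make_reference()] result (rebuilt
#'   from the config when NULL).
#' @return List of class `shm_simulation`: `clones` (clone tibble),
#'   `truth_clones` (`clone_id`, `allele`, `j_id`, `template`),
#'   `truth_mutations` (`clone_id`, `position` in template coordinates,
#'   `from`, `to`, `class`, `motif_class`), `reference`, `config`.
#' @export
simulate_repertoire <- function(config, reference = NULL) {
  stopifnot(inherits(config, "shm_sim_config"))
  if (is.null(reference)) reference <- make_reference(config)
  set.seed(config$seed + 1L)
  max_bias <- max(config$base_bias) * max(c(config$motif_multipliers, 1))
  if (config$mutation_rate * max_bias > 1) {
    stop_shm("config error: per-site hazard exceeds 1")
  }
  n <- config$n_clones
  clones <- vector("list", n)
  truth_clones <- vector("list", n)
  truth_muts <- vector("list", n)
  motif_cache <- new.env(parent = emptyenv())
  cached_scan <- function(template) {
    key <- paste0("k", substr(template, 1, 24), nchar(template))
    hit <- get0(key, envir = motif_cache)
    if (is.null(hit) || !identical(attr(hit, "template"), template)) {
      hit <- scan_motifs(template)
      attr(hit, "template") <- template
      assign(key, hit, envir = motif_cache)
    }
    hit
  }
  for (i in seq_len(n)) {
    allele <- if (config$heterozygous &&
                  stats::runif(1) > config$allele_ratio) "B" else "A"
    cseq <- if (allele == "B") reference$c_b else reference$c_a
    if (config$v_length > 0) {
      ji <- sample.int(nrow(reference$j_library), 1)
      j_id <- reference$j_library$j_id[ji]
      jseq <- reference$j_library$sequence[ji]
      r <- config$junction_indel_range
      t_v <- sample.int(r + 1L, 1) - 1L
      t_j <- sample.int(r + 1L, 1) - 1L
      # additions restore the reading frame (expressed CDR3 length
      # variation is in-frame); no variation at all when the range is 0
      n_add <- if (r > 0) {
        (t_v + t_j) %% 3L + 3L * (sample.int(2L, 1) - 1L)
      } else 0L
      add <- paste(sample(DNA_BASES, n_add, replace = TRUE), collapse = "")
      template <- paste0(substr(reference$v, 1, config$v_length - t_v),
                         add,
                         substr(jseq, t_j + 1, nchar(jseq)),
                         cseq)
    } else {
      j_id <- NA_character_
      template <- cseq
    }
    tch <- seq_chars(template)
    L <- length(tch)
    mult <- motif_multiplier_vector(template, config$motif_multipliers)
    hazard <- config$mutation_rate * config$base_bias[tch] * mult
    hit <- which(stats::runif(L) < hazard)
    mch <- tch
    muts <- NULL
    if (length(hit)) {
      to <- vapply(hit, function(p) {
        if (stats::runif(1) < config$transition_prob) TRANSITION_OF[[tch[p]]]
        else sample(TRANSVERSIONS_OF[[tch[p]]], 1)
      }, character(1))
      mch[hit] <- to
      hits_here <- cached_scan(template)
      mclass <- vapply(hit, function(p) {
        sel <- hits_here$mutable_position == p - 1L
        if (any(sel)) paste(sort(unique(hits_here$motif_class[sel])),
                            collapse = ",") else ""
      }, character(1))
      muts <- tibble::new_tibble(list(
        clone_id = rep(sprintf("sim%03d", i), length(hit)),
        position = hit - 1L,
        from = unname(tch[hit]), to = unname(to),
        class = rep("substitution", length(hit)),
        motif_class = mclass
      ), nrow = length(hit))
    }
    n_del <- stats::rpois(1, config$indel_rate)
    if (n_del > 0) {
      del_pos <- sort(sample.int(L, min(n_del, L)))
      muts <- dplyr::bind_rows(muts, tibble::tibble(
        clone_id = sprintf("sim%03d", i), position = del_pos - 1L,
        from = unname(tch[del_pos]), to = "", class = "deletion",
        motif_class = ""
      ))
      mch <- mch[-del_pos]
    }
    clones[[i]] <- tibble::tibble(
      clone_id = sprintf("sim%03d", i), individual_id = "SIM",
      tissue = "sim", sequence = paste(mch, collapse = "")
    )
    truth_clones[[i]] <- tibble::tibble(
      clone_id = sprintf("sim%03d", i), allele = allele, j_id = j_id,
      template = template
    )
    truth_muts[[i]] <- muts
  }
  structure(list(
    clones = dplyr::bind_rows(clones),
    truth_clones = dplyr::bind_rows(truth_clones),
    truth_mutations = dplyr::bind_rows(truth_muts),
    reference = reference, config = config
  ), class = "shm_simulation")
}

#' Compare pipeline mutation calls with simulator truth
#'
#' Substitution calls are matched to planted substitutions on
#' (clone, position, target base).
#'
#' @param records Mutation-record tibble from [call_mutations()] run
#'   against each clone's template (truth coordinates).
#' @param sim `shm_simulation` object.
#' @return One-row tibble: `n_called`, `n_truth`, `n_matched`,
#'   `precision`, `recall`.
#' @export
truth_compare <- function(records, sim) {
  if (!all(records$clone_id %in% sim$truth_clones$clone_id)) {
    stop_shm("mismatched clone ids between records and truth")
  }
  called <- records[records$event_class == "substitution",
                    c("clone_id", "position", "to_base")]
  truth <- sim$truth_mutations
  truth <- truth[truth$class == "substitution",
                 c("clone_id", "position", "to")]
  key <- function(id, pos, to) paste(id, pos, to, sep = ":")
  ck <- key(called$clone_id, called$position, called$to_base)
  tk <- key(truth$clone_id, truth$position, truth$to)
  matched <- sum(ck %in% tk)
  tibble::tibble(
    n_called = nrow(called), n_truth = nrow(truth), n_matched = matched,
    precision = if (nrow(called)) matched / nrow(called) else NA_real_,
    recall = if (nrow(truth)) matched / nrow(truth) else NA_real_
  )
}
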
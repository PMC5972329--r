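# Mutation calling and classification against the (sub)group germline:
# per-event records, Table-shaped summaries, 20-bp window profiles,
# functional status and rate contrasts.

#' Call and classify mutations in a clone set
#'
#' Each clone is aligned to `germline` and one record is emitted per
#' substitution column and per contiguous gap run. Positions recorded as
#' allelic in the germline are skipped (they are allotypic, not somatic),
#' as are masked spans (e.g. primer-covered bases) and columns where either
#' sequence carries N. The coding effect of a substitution is computed by
#' translating the germline codon with only that substitution applied;
#' substitutions creating a stop are `nonsense`; substitutions downstream
#' of a frameshifting indel are still called at the nucleotide level with
#' `effect = "noncoding"`.
#'
#' @param clones Clone tibble.
#' @param germline `shm_germline` object (or plain reference string).
#' @param rmap Optional `shm_region_map` for region labels and frame.
#' @param masked_spans Optional tibble `start`,`end` (0-based half-open) of
#'   reference spans excluded from calling and from the surveyed-base count.
#' @return Tibble of mutation records: `clone_id`, `position` (0-based
#'   reference), `from_base`, `to_base`, `event_class`, `length`, `titv`,
#'   `effect`, `region`. Attribute `surveyed` holds a tibble
#'   (`clone_id`, `n_bp`) of surveyed reference-aligned bases per clone.
#' @export
call_mutations <- function(clones, germline, rmap = NULL, masked_spans = NULL) {
  check_clone_tbl(clones)
  if (is.character(germline)) germline <- germline_reference(germline)
  ref <- germline$sequence
  frame <- if (!is.null(rmap)) rmap$frame_offset else germline$frame_offset
  refc <- seq_chars(ref)
  mask <- mask_vector(nchar(ref), masked_spans)
  allelic <- germline$allelic_positions$position
  code <- Biostrings::GENETIC_CODE

  res <- purrr::map(seq_len(nrow(clones)), function(i) {
    if (nchar(clones$sequence[i]) < nchar(ref) / 2) {
      warning("fragment: clone ", clones$clone_id[i],
              " shorter than half the germline; processed over aligned span",
              call. = FALSE)
    }
    al <- align_clone(clones$sequence[i], ref)
    ev <- al$events
    surveyed_cols <- al$columns$ref_pos[
      !is.na(al$columns$ref_pos) & al$columns$clone_base != "-" &
        al$columns$ref_base != "N" & al$columns$clone_base != "N"]
    n_bp <- sum(!mask[surveyed_cols + 1L])
    if (nrow(ev) == 0) {
      return(list(records = NULL, n_bp = n_bp))
    }
    ev <- ev[!(ev$event_class == "substitution" & ev$ref_start %in% allelic), ,
             drop = FALSE]
    ev <- ev[is.na(ev$ref_start) | !mask[pmax(ev$ref_start, 0L) + 1L], ,
             drop = FALSE]
    if (nrow(ev) == 0) return(list(records = NULL, n_bp = n_bp))

    ev <- dplyr::arrange(ev, .data$ref_start)
    indel <- ev$event_class != "substitution"
    signed <- ifelse(ev$event_class == "insertion", ev$length,
                     ifelse(ev$event_class == "deletion", -ev$length, 0L))
    net_before <- cumsum(signed) - signed   # net indel length 5' of event
    shifted <- (net_before %% 3L) != 0L

    effect <- character(nrow(ev))
    titv <- rep("n/a", nrow(ev))
    for (k in seq_len(nrow(ev))) {
      if (indel[k]) {
        effect[k] <- if (ev$length[k] %% 3L != 0L) "frameshift" else "noncoding"
        next
      }
      p <- ev$ref_start[k]
      titv[k] <- if (is_transition(ev$from_base[k], ev$to_base[k]))
        "transition" else "transversion"
      if (shifted[k] || p < frame) { effect[k] <- "noncoding"; next }
      ci <- (p - frame) %/% 3L
      cs <- frame + 3L * ci
      if (cs + 3L > nchar(ref)) { effect[k] <- "noncoding"; next }
      codon <- refc[(cs + 1L):(cs + 3L)]
      if (any(!codon %in% DNA_BASES)) { effect[k] <- "noncoding"; next }
      mutant <- codon
      mutant[p - cs + 1L] <- ev$to_base[k]
      aa0 <- code[[paste(codon, collapse = "")]]
      aa1 <- code[[paste(mutant, collapse = "")]]
      effect[k] <- if (aa1 == aa0) "synonymous"
        else if (aa1 == "*") "nonsense" else "replacement"
    }
    n_ev <- nrow(ev)
    list(records = tibble::new_tibble(list(
      clone_id = rep(clones$clone_id[i], n_ev),
      position = ev$ref_start,
      from_base = ev$from_base,
      to_base = ev$to_base,
      event_class = ev$event_class,
      length = ev$length,
      titv = titv,
      effect = effect,
      region = region_of(ev$ref_start, rmap)
    ), nrow = n_ev), n_bp = n_bp)
  })

  records <- dplyr::bind_rows(purrr::map(res, "records"))
  if (nrow(records) == 0) {
    records <- tibble::tibble(
      clone_id = character(0), position = integer(0),
      from_base = character(0), to_base = character(0),
      event_class = character(0), length = integer(0),
      titv = character(0), effect = character(0), region = character(0)
    )
  }
  attr(records, "surveyed") <- tibble::tibble(
    clone_id = clones$clone_id,
    n_bp = vapply(res, function(r) as.integer(r$n_bp), integer(1))
  )
  records
}

#' Summarize mutation records into a per-individual report row
#'
#' Counts and ratios over one clone group (an individual or a pool).
#' `replacement` includes nonsense substitutions (they change the protein);
#' frameshifts are counted in `n_events` but never as transitions or
#' transversions, so `replacement + silent + noncoding_subs + frameshifts =
#' n_events` and `transitions + transversions + frameshifts +
#' in_frame_indels = n_events`. Ratios are returned at full precision;
#' printed report columns truncate to two decimals via [printed_value()].
#'
#' @param records Mutation-record tibble from [call_mutations()].
#' @param n_bp Total surveyed reference-aligned bases for the group.
#' @param n_clones Number of clones in the group.
#' @param label Group label (individual id or "Total").
#' @return One-row tibble of class `shm_summary`.
#' @export
summarize_mutations <- function(records, n_bp, n_clones = NA_integer_,
                                label = "all") {
  if (n_bp <= 0) stop_shm("n_bp must be positive")
  subs <- records[records$event_class == "substitution", , drop = FALSE]
  indels <- records[records$event_class != "substitution", , drop = FALSE]
  n_events <- nrow(records)
  repl <- sum(subs$effect %in% c("replacement", "nonsense"))
  silent <- sum(subs$effect == "synonymous")
  ti <- sum(subs$titv == "transition")
  tv <- sum(subs$titv == "transversion")
  fs <- sum(indels$effect == "frameshift")
  out <- tibble::tibble(
    label = label,
    n_clones = as.integer(n_clones),
    n_bp = as.integer(n_bp),
    n_events = n_events,
    freq_per_kb = 1000 * n_events / n_bp,
    replacement = repl,
    silent = silent,
    nonsense = sum(subs$effect == "nonsense"),
    transitions = ti,
    transversions = tv,
    frameshifts = fs,
    rs_ratio = if (silent > 0) repl / silent else NA_real_,
    titv_ratio = if (tv > 0) ti / tv else NA_real_
  )
  class(out) <- c("shm_summary", class(out))
  out
}

#' Per-region mutation breakdown
#'
#' @param records Mutation-record tibble with a `region` column.
#' @return Tibble `region`, `replacement`, `silent`, `n_events`.
#' @export
region_breakdown <- function(records) {
  records |>
    dplyr::filter(!is.na(.data$region)) |>
    dplyr::group_by(region = .data$region) |>
    dplyr::summarise(
      replacement = sum(.data$effect %in% c("replacement", "nonsense")),
      silent = sum(.data$effect == "synonymous"),
      n_events = dplyr::n(),
      .groups = "drop"
    )
}

#' Per-window mutation frequency profile
#'
#' Non-overlapping windows of `window` bp from the first unmasked analyzed
#' position. The frequency of an effect class in a window is the event
#' count over all clones divided by (unmasked positions in the window x
#' number of clones covering it). Events at masked positions (e.g. primer
#' spans) are excluded everywhere.
#'
#' @param records Mutation-record tibble.
#' @param n_clones Clones covering the reference (scalar).
#' @param ref_length Reference length in bp.
#' @param window Window size in bp (default 20).
#' @param masked_spans Optional masked spans tibble.
#' @param classes Effect classes to profile.
#' @return Tibble `window_start`, `window_end`, `window_start_1based`,
#'   `class`, `count`, `frequency`.
#' @export
window_profile <- function(records, n_clones, ref_length, window = 20,
                           masked_spans = NULL,
                           classes = c("replacement", "silent")) {
  if (window < 1) stop_shm("window must be >= 1")
  mask <- mask_vector(ref_length, masked_spans)
  first <- which(!mask)[1]
  if (is.na(first)) stop_shm("reference fully masked")
  starts <- seq(first - 1L, ref_length - 1L, by = window)
  subs <- records[records$event_class == "substitution" &
                    !mask[records$position + 1L], , drop = FALSE]
  eff <- ifelse(subs$effect == "nonsense", "replacement",
                ifelse(subs$effect == "synonymous", "silent", subs$effect))
  purrr::map_dfr(starts, function(s) {
    e <- min(s + window, ref_length)
    len <- sum(!mask[(s + 1L):e])
    in_win <- subs$position >= s & subs$position < e
    purrr::map_dfr(classes, function(cl) {
      cnt <- sum(in_win & eff == cl)
      tibble::tibble(
        window_start = s, window_end = e,
        window_start_1based = s + 1L,
        class = cl, count = cnt,
        frequency = if (len > 0) cnt / (len * n_clones) else NA_real_
      )
    })
  })
}

#' Functional status of each clone
#'
#' A clone is `frameshift` when the net indel length upstream of the
#' constant region is not a multiple of 3; otherwise `stop_codon` when its
#' translation carries a premature stop; otherwise `in_frame`.
#'
#' @param clones Clone tibble.
#' @param germline `shm_germline` or reference string.
#' @param rmap Optional region map; the constant region starts at the first
#'   `C-*` region (indels 3' of it cannot frameshift the receptor ORF).
#' @return Tibble `clone_id`, `status`.
#' @export
functional_status <- function(clones, germline, rmap = NULL) {
  check_clone_tbl(clones)
  if (is.character(germline)) germline <- germline_reference(germline)
  frame <- if (!is.null(rmap)) rmap$frame_offset else germline$frame_offset
  c_start <- Inf
  if (!is.null(rmap)) {
    cr <- rmap$regions[startsWith(rmap$regions$name, "C-"), , drop = FALSE]
    if (nrow(cr)) c_start <- min(cr$start)
  }
  status <- vapply(seq_len(nrow(clones)), function(i) {
    al <- align_clone(clones$sequence[i], germline$sequence)
    ev <- al$events
    ind <- ev[ev$event_class != "substitution" & ev$ref_start < c_start, ,
              drop = FALSE]
    net <- sum(ifelse(ind$event_class == "insertion", ind$length, -ind$length))
    if (net %% 3L != 0L) return("frameshift")
    aa <- translate_nt(clones$sequence[i], frame)
    stops <- which(aa == "*")
    if (length(stops) && any(stops < length(aa))) return("stop_codon")
    "in_frame"
  }, character(1))
  tibble::tibble(clone_id = clones$clone_id, status = status)
}

#' Fraction of non-functional clones
#'
#' @param status Tibble from [functional_status()] or a status vector.
#' @return Fraction of clones not `in_frame`.
#' @export
nonfunctional_fraction <- function(status) {
  s <- if (is.data.frame(status)) status$status else status
  mean(s != "in_frame")
}

#' Contrast mutation rates of a target and a control gene
#'
#' Rate ratio of events per kb with a conditional binomial test: given the
#' total events, the target's share is binomial with success probability
#' equal to its share of surveyed bases.
#'
#' @param n_target,bp_target Events and surveyed bp in the target.
#' @param n_control,bp_control Events and surveyed bp in the control.
#' @return One-row tibble: `rate_target`, `rate_control` (per kb), `ratio`
#'   (NA with `note` when undefined), `p_value`.
#' @export
compare_rates <- function(n_target, bp_target, n_control, bp_control) {
  if (bp_target <= 0 || bp_control <= 0) stop_shm("surveyed bp must be positive")
  rt <- 1000 * n_target / bp_target
  rc <- 1000 * n_control / bp_control
  note <- NA_character_
  if (n_target + n_control == 0) {
    ratio <- NA_real_; p <- NA_real_; note <- "no events in either group"
  } else {
    ratio <- if (rc > 0) rt / rc else NA_real_
    if (rc == 0) note <- "zero control events: ratio undefined"
    p <- stats::binom.test(n_target, n_target + n_control,
                           p = bp_target / (bp_target + bp_control))$p.value
  }
  tibble::tibble(rate_target = rt, rate_control = rc, ratio = ratio,
                 p_value = p, note = note)
}
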
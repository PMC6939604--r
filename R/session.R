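#' @keywords internal
"_PACKAGE"

#' @useDynLib cptddm, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Task timing constants (ms): 250 ms stimulus + 1400 ms interstimulus
# interval; responses accepted until onset of the next stimulus.
CPT_STIMULUS_MS <- 250
CPT_ISI_MS <- 1400
CPT_DEADLINE_MS <- CPT_STIMULUS_MS + CPT_ISI_MS

#' Generate a pseudorandomised CPT-AX trial sequence
#'
#' Builds one 400-trial cued continuous performance task session: four
#' blocks of 100 trials, each containing 10 go trials (a cue immediately
#' followed by the target), 10 cue-without-target ("cue only") trials, 10
#' uncued-target trials and filler distractors drawn from 11 distractor
#' shapes. Go trials therefore make up 10% of the session (40 of 400) and
#' the remaining 360 trials are no-go.
#'
#' Pseudorandomisation enforces, per block: the fixed category counts; go
#' pairs that do not overlap and are separated by at least two intervening
#' trials; no cue-only trial immediately followed by a target stimulus
#' (which would create an unintended go pair), including across block
#' boundaries. Block orders differ from one another within a session.
#'
#' @param seed integer RNG seed; identical seeds give identical sessions.
#' @return A data frame of class `"cpt_session"` with 400 rows and columns
#'   `block_index`, `trial_index` (1-100 within block), `stimulus_role`
#'   (`"cue"`, `"target"`, `"distractor_1"` ... `"distractor_11"`),
#'   `trial_type` (`"go"`, `"cue_only"`, `"uncued_target"`, `"filler"`),
#'   `responded` (logical, `FALSE` until responses are simulated or
#'   observed) and `rt_ms` (`NA` when no response). Timing constants are
#'   attached as attributes `stimulus_duration_ms`, `isi_ms`, `deadline_ms`
#'   and `seed`.
#' @examples
#' s <- generate_trial_sequence(seed = 1)
#' table(s$trial_type)
#' @export
generate_trial_sequence <- function(seed) {
  stopifnot(length(seed) == 1L, is.finite(seed))
  set.seed(as.integer(seed))
  blocks <- vector("list", 4L)
  for (b in 1:4) blocks[[b]] <- make_block(b)
  out <- do.call(rbind, blocks)
  rownames(out) <- NULL
  attr(out, "stimulus_duration_ms") <- CPT_STIMULUS_MS
  attr(out, "isi_ms") <- CPT_ISI_MS
  attr(out, "deadline_ms") <- CPT_DEADLINE_MS
  attr(out, "seed") <- as.integer(seed)
  class(out) <- c("cpt_session", "data.frame")
  out
}

# One 100-trial block. Go-pair cue positions are sampled uniformly over
# start sets with pairwise spacing >= 4 (two intervening trials between
# consecutive pairs) via the order-statistics shift trick; cue-only and
# uncued-target placements are rejection-sampled against the adjacency
# constraints.
make_block <- function(block_index) {
  starts <- sort(sample.int(63L, 10L)) + 4L * (0:9)   # in 1..99, gaps >= 4
  occupied <- c(starts, starts + 1L)
  free <- setdiff(1:100, occupied)
  repeat {
    picks <- sample(free, 20L)
    cue_only <- picks[1:10]
    uncued <- picks[11:20]
    if (!any((cue_only + 1L) %in% uncued) && !(100L %in% cue_only)) break
  }
  role <- rep(NA_character_, 100L)
  type <- rep("filler", 100L)
  role[starts] <- "cue"
  role[starts + 1L] <- "target"
  type[starts + 1L] <- "go"
  role[cue_only] <- "cue"
  type[cue_only] <- "cue_only"
  role[uncued] <- "target"
  type[uncued] <- "uncued_target"
  filler <- which(is.na(role))
  role[filler] <- paste0("distractor_", sample.int(11L, length(filler),
                                                   replace = TRUE))
  data.frame(block_index = block_index, trial_index = 1:100,
             stimulus_role = role, trial_type = type,
             responded = FALSE, rt_ms = NA_real_,
             stringsAsFactors = FALSE)
}

#' Validate the structural invariants of a CPT-AX session
#'
#' Checks the 4 x 100 block structure, per-block category counts
#' (10 go / 10 cue-only / 10 uncued-target), the session totals (40 go,
#' 360 no-go), the consistency of `responded` with `rt_ms`, and that every
#' go trial is a target immediately preceded by a cue.
#'
#' @param session a `"cpt_session"` data frame (or any data frame with the
#'   same columns).
#' @return Invisibly `TRUE`; throws an informative error on violation.
#' @export
validate_session <- function(session) {
  need <- c("block_index", "trial_index", "stimulus_role", "trial_type",
            "responded", "rt_ms")
  if (!all(need %in% names(session)))
    stop("session is missing columns: ",
         paste(setdiff(need, names(session)), collapse = ", "), call. = FALSE)
  if (nrow(session) != 400L)
    stop("session must have 400 trials, found ", nrow(session), call. = FALSE)
  tab <- table(session$block_index)
  if (length(tab) != 4L || any(tab != 100L))
    stop("session must have 4 blocks of 100 trials", call. = FALSE)
  for (b in unique(session$block_index)) {
    tt <- session$trial_type[session$block_index == b]
    cnt <- c(go = sum(tt == "go"), cue_only = sum(tt == "cue_only"),
             uncued = sum(tt == "uncued_target"))
    if (any(cnt != 10L))
      stop("block ", b, ": expected 10 go / 10 cue_only / 10 uncued_target, ",
           "got ", paste(cnt, collapse = "/"), call. = FALSE)
  }
  go <- which(session$trial_type == "go")
  bad_go <- go[session$stimulus_role[go] != "target" |
               go == 1L | session$stimulus_role[pmax(go - 1L, 1L)] != "cue"]
  if (length(bad_go))
    stop("go trials must be targets immediately preceded by a cue ",
         "(rows ", paste(bad_go, collapse = ", "), ")", call. = FALSE)
  resp <- session$responded
  if (any(resp & is.na(session$rt_ms)) || any(!resp & !is.na(session$rt_ms)))
    stop("rt_ms must be present exactly when responded is TRUE", call. = FALSE)
  if (any(session$rt_ms <= 0, na.rm = TRUE))
    stop("rt_ms must be positive", call. = FALSE)
  invisible(TRUE)
}

#' @export
print.cpt_session <- function(x, ...) {
  cat("CPT-AX session:", nrow(x), "trials,",
      sum(x$trial_type == "go"), "go /",
      sum(x$trial_type != "go"), "no-go;",
      "deadline", attr(x, "deadline_ms"), "ms\n")
  cat("responses recorded:", sum(x$responded), "\n")
  invisible(x)
}
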
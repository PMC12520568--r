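## Cytosine states tracked through a conversion protocol.  "T" is the
## terminal deaminated/converted state (reads as thymine); every other
## state still carries a cytosine base and reads as C on the sequencer.
.CYTOSINE_STATES <- c("C", "5mC", "5hmC", "5gmC", "5fC", "5caC", "5ghmC")
.TERMINAL_T <- "T"
.ENZYME_STEPS <- c("CMD1", "BGT", "TET", "DEA", "BISULFITE")
.PROTOCOLS <- c("BS", "TAB", "ACE", "CD", "CT")

#' Known cytosine modification states
#'
#' The closed set of chemical identities a cytosine can take while moving
#' through a conversion protocol: unmodified C, 5-methylcytosine (5mC),
#' 5-hydroxymethylcytosine (5hmC), 5-glyceryl-methylcytosine (5gmC, the
#' CMD1 product of 5mC), 5-formyl/5-carboxylcytosine (5fC/5caC, TET
#' oxidation products), and beta-glucosyl-5-hydroxymethylcytosine (5ghmC,
#' the betaGT product of 5hmC).
#'
#' @return Character vector of state labels.
#' @export
cytosine_states <- function() .CYTOSINE_STATES

#' Default chemistry efficiencies
#'
#' Per-enzyme, per-substrate conversion efficiencies used by
#' [prob_read_C()] and the pileup simulator.  Values are calibrated to the
#' achieved spike-in rates of the assays rather than mechanistic per-enzyme
#' constants: CD-seq deaminates ~97% of 5hmC and retains ~93% of 5mC
#' (the whole 5mC loss is attributed to incomplete CMD1 glycerylation, with
#' 5gmC treated as fully deaminase/bisulfite resistant), and TAB-seq leaves
#' ~2% of 5mC unoxidised so it reads as C.  Every entry is a probability in
#' \[0,1\] and can be overridden by editing the returned list.
#'
#' `seq_error` is a symmetric C<->T flip applied after the chemistry,
#' lumping sequencer and residual library noise.
#'
#' @return Named list with one named numeric vector per enzymatic step
#'   (`cmd1`, `bgt`, `tet`, `dea`, `bisulfite`) plus `seq_error`.
#' @export
default_chemistry_config <- function() {
  list(
    ## CMD1 glycerylates 5mC -> 5gmC; does not touch 5hmC.
    cmd1 = c("5mC" = 0.93),
    ## betaGT glucosylates 5hmC -> 5ghmC; 5mC minimally affected.
    bgt = c("5hmC" = 0.98),
    ## TET oxidises 5mC and (unprotected) 5hmC to 5fC/5caC, collapsed
    ## to 5caC since neither is ever read out separately.
    tet = c("5mC" = 0.98, "5hmC" = 0.95),
    ## Deaminase mix: converts C, 5mC, 5hmC (and any 5fC/5caC) to a T
    ## readout; bulky 5gmC/5ghmC resist (efficiency 0).
    dea = c("C" = 0.995, "5mC" = 0.995, "5hmC" = 0.97,
            "5fC" = 1, "5caC" = 1, "5gmC" = 0, "5ghmC" = 0),
    ## Bisulfite converts C, 5fC, 5caC to T; 5mC/5hmC and the bulky
    ## adducts are protected.
    bisulfite = c("C" = 0.995, "5fC" = 1, "5caC" = 1,
                  "5mC" = 0, "5hmC" = 0, "5gmC" = 0, "5ghmC" = 0),
    seq_error = 0.001
  )
}

#' Idealised chemistry (all conversions complete, no noise)
#'
#' Every should-convert efficiency is 1, every protected state is fully
#' protected, and the sequencing error is 0.  Under this configuration each
#' protocol realises its design truth table exactly (see [truth_table()]).
#'
#' @return Config list in the same shape as [default_chemistry_config()].
#' @export
ideal_chemistry_config <- function() {
  cfg <- default_chemistry_config()
  cfg$cmd1[] <- 1
  cfg$bgt[] <- 1
  cfg$tet[] <- 1
  cfg$dea[c("C", "5mC", "5hmC", "5fC", "5caC")] <- 1
  cfg$dea[c("5gmC", "5ghmC")] <- 0
  cfg$bisulfite[c("C", "5fC", "5caC")] <- 1
  cfg$bisulfite[c("5mC", "5hmC", "5gmC", "5ghmC")] <- 0
  cfg$seq_error <- 0
  cfg
}

## product state of each enzymatic step, per substrate
.STEP_PRODUCT <- list(
  CMD1      = c("5mC" = "5gmC"),
  BGT       = c("5hmC" = "5ghmC"),
  TET       = c("5mC" = "5caC", "5hmC" = "5caC"),
  DEA       = c("C" = "T", "5mC" = "T", "5hmC" = "T",
                "5fC" = "T", "5caC" = "T", "5gmC" = "T", "5ghmC" = "T"),
  BISULFITE = c("C" = "T", "5fC" = "T", "5caC" = "T",
                "5mC" = "T", "5hmC" = "T", "5gmC" = "T", "5ghmC" = "T")
)

.STEP_CONFIG_KEY <- c(CMD1 = "cmd1", BGT = "bgt", TET = "tet",
                      DEA = "dea", BISULFITE = "bisulfite")

#' Built-in conversion protocols
#'
#' Returns the ordered enzymatic steps of one of the five supported
#' chemistries:
#' \describe{
#'   \item{BS}{bisulfite only; 5mC and 5hmC both read C.}
#'   \item{TAB}{betaGT protection of 5hmC, TET oxidation of 5mC,
#'     bisulfite; only 5hmC reads C.}
#'   \item{ACE}{betaGT protection of 5hmC, deaminase; only 5hmC reads C.}
#'   \item{CD}{CMD1 glycerylation of 5mC, deaminase; only 5mC reads C.}
#'   \item{CT}{CMD1 glycerylation of 5mC, TET oxidation of 5hmC,
#'     bisulfite; only 5mC reads C.}
#' }
#'
#' @param name Protocol name, one of `"BS"`, `"TAB"`, `"ACE"`, `"CD"`,
#'   `"CT"`.
#' @return An object of class `assay_protocol`: a list with `name` and the
#'   ordered character vector `steps`.
#' @export
assay_protocol <- function(name) {
  if (inherits(name, "assay_protocol")) return(name)
  if (!is.character(name) || length(name) != 1L || !(name %in% .PROTOCOLS))
    stop("unknown protocol: ", paste(name, collapse = ","),
         " (expected one of ", paste(.PROTOCOLS, collapse = ", "), ")")
  steps <- switch(name,
    BS  = c("BISULFITE"),
    TAB = c("BGT", "TET", "BISULFITE"),
    ACE = c("BGT", "DEA"),
    CD  = c("CMD1", "DEA"),
    CT  = c("CMD1", "TET", "BISULFITE"))
  structure(list(name = name, steps = steps), class = "assay_protocol")
}

#' @export
print.assay_protocol <- function(x, ...) {
  cat("<assay_protocol>", x$name, ":", paste(x$steps, collapse = " -> "),
      "-> readout\n")
  invisible(x)
}

.check_config <- function(config) {
  for (key in c("cmd1", "bgt", "tet", "dea", "bisulfite")) {
    v <- config[[key]]
    if (is.null(v)) stop("chemistry config is missing step '", key, "'")
    if (any(v < 0 | v > 1))
      stop("chemistry config step '", key, "' has efficiency outside [0,1]")
  }
  if (!is.null(config$seq_error) &&
      (config$seq_error < 0 || config$seq_error > 1))
    stop("chemistry config 'seq_error' outside [0,1]")
  invisible(TRUE)
}

## Apply one enzymatic step to a probability vector over states.
.apply_step <- function(p, step, config) {
  eff <- config[[.STEP_CONFIG_KEY[[step]]]]
  prod <- .STEP_PRODUCT[[step]]
  for (substrate in names(prod)) {
    e <- if (substrate %in% names(eff)) unname(eff[[substrate]]) else 0
    if (e == 0) next
    moved <- p[[substrate]] * e
    p[[substrate]] <- p[[substrate]] - moved
    p[[prod[[substrate]]]] <- p[[prod[[substrate]]]] + moved
  }
  p
}

#' Probability that a cytosine state is read as C
#'
#' Propagates a single cytosine of known chemical state through the ordered
#' enzymatic steps of a protocol, treating steps as sequentially applied
#' independent Bernoulli conversions, and returns the marginal probability
#' that the sequenced base is C.  Closed-form (no sampling); states that
#' survive as a cytosine derivative read C, the deaminated/converted
#' terminal reads T.  The symmetric `seq_error` flip is *not* applied here
#' (see [apply_seq_error()]); this is the pure chemistry probability.
#'
#' @param state One of [cytosine_states()].
#' @param protocol Protocol name or [assay_protocol()] object.
#' @param config Chemistry config, default [default_chemistry_config()].
#' @return Probability in \[0,1\].
#' @examples
#' prob_read_C("5mC", "CD", ideal_chemistry_config())   # 1: 5gmC resists
#' prob_read_C("5hmC", "CD", ideal_chemistry_config())  # 0: deaminated
#' @export
prob_read_C <- function(state, protocol, config = default_chemistry_config()) {
  if (length(state) > 1L)
    return(vapply(state, prob_read_C, numeric(1),
                  protocol = protocol, config = config))
  if (!(state %in% .CYTOSINE_STATES))
    stop("unknown cytosine state: ", state)
  protocol <- assay_protocol(protocol)
  .check_config(config)
  p <- stats::setNames(numeric(length(.CYTOSINE_STATES) + 1L),
                       c(.CYTOSINE_STATES, .TERMINAL_T))
  p[[state]] <- 1
  p <- as.list(p)
  for (step in protocol$steps) {
    if (!(step %in% .ENZYME_STEPS)) stop("unknown enzymatic step: ", step)
    p <- .apply_step(p, step, config)
  }
  1 - p[[.TERMINAL_T]]
}

#' Apply the symmetric sequencing-error flip to a read-C probability
#'
#' @param p Probability of reading C after chemistry.
#' @param seq_error Symmetric C<->T flip probability.
#' @return Adjusted probability `p (1 - e) + (1 - p) e`.
#' @export
apply_seq_error <- function(p, seq_error) {
  stopifnot(all(p >= 0 & p <= 1), seq_error >= 0, seq_error <= 1)
  p * (1 - seq_error) + (1 - p) * seq_error
}

#' Expected raw C-fraction at a site with modification levels (m, h)
#'
#' A site where a fraction `m` of molecules carry 5mC, `h` carry 5hmC and
#' the rest are unmodified has expected converted-read C-fraction
#' `m P_C(5mC) + h P_C(5hmC) + (1 - m - h) P_C(C)` under the given
#' protocol.  Vectorised over `m` and `h`.
#'
#' @param m,h 5mC and 5hmC molecule fractions, `m + h <= 1`.
#' @param protocol Protocol name or object.
#' @param config Chemistry config.
#' @param seq_error Optional override of the config's symmetric flip; use
#'   `0` for the pure chemistry expectation.
#' @return Expected C-fraction(s) in \[0,1\].
#' @export
expected_raw_level <- function(m, h, protocol,
                               config = default_chemistry_config(),
                               seq_error = config$seq_error) {
  if (any(m < 0) || any(h < 0)) stop("m and h must be non-negative")
  if (any(m + h > 1 + 1e-12)) stop("m + h exceeds 1 at some site")
  pC <- prob_read_C(c("C", "5mC", "5hmC"), protocol, config)
  lvl <- m * pC[["5mC"]] + h * pC[["5hmC"]] + (1 - m - h) * pC[["C"]]
  if (is.null(seq_error)) seq_error <- 0
  apply_seq_error(pmin(pmax(lvl, 0), 1), seq_error)
}

#' Ideal readout truth table of a protocol
#'
#' The base each of C, 5mC and 5hmC is read as when every conversion in the
#' protocol is complete: e.g. CD and CT read 5mC as C and everything else
#' as T, while TAB and ACE read 5hmC as C and everything else as T.
#'
#' @param protocol Protocol name or object.
#' @return Named character vector over `c("C","5mC","5hmC")` with values
#'   `"C"` or `"T"`.
#' @export
truth_table <- function(protocol) {
  states <- c("C", "5mC", "5hmC")
  p <- prob_read_C(states, protocol, ideal_chemistry_config())
  stats::setNames(ifelse(p >= 0.5, "C", "T"), states)
}

#' Effective readout probabilities of a protocol
#'
#' Convenience summary: the probability each cytosine state reads C under a
#' chemistry configuration, with and without the sequencing-error flip.
#'
#' @param protocol Protocol name or object.
#' @param config Chemistry config.
#' @return `data.frame` with one row per state.
#' @export
chemistry_table <- function(protocol, config = default_chemistry_config()) {
  protocol <- assay_protocol(protocol)
  p <- prob_read_C(.CYTOSINE_STATES, protocol, config)
  data.frame(
    state = .CYTOSINE_STATES,
    prob_read_C = unname(p),
    prob_read_C_with_error = unname(apply_seq_error(p, config$seq_error)),
    row.names = NULL
  )
}
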
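#' Simulation parameters
#'
#' Constructs the full parameter set of the model. Every argument is a
#' per-step Bernoulli probability (or a count / factor) with the published
#' default value. `P_NFR` and `P_TLR`, the ribozyme-catalysed rates, default
#' to 0: they take their active values (0.2 and 0.9) only in scenarios that
#' model the corresponding ribozyme.
#'
#' @param P_AT probability that an RNA template attracts a substrate.
#' @param P_BB probability that a phosphodiester bond breaks (single-strand
#'   region); in a duplex region both parallel bonds break together at
#'   `P_BB^(3/2)`.
#' @param P_CIC chirality interconversion (racemization) of a nucleotide
#'   precursor. Only precursors racemize; nucleotides and residues never do.
#' @param P_FP false base-pairing factor applied per mismatched position
#'   when a template attracts a substrate.
#' @param P_MN movement of a free nucleotide; an m-residue RNA moves at
#'   `P_MN / sqrt(m)` (Zimm-type size dependence).
#' @param P_MPN movement of a nucleotide precursor.
#' @param P_ND decay of a free nucleotide into its precursor.
#' @param P_NDE decay of a nucleotide residue at a chain end; a duplex end
#'   loses both paired residues together at `P_NDE^(3/2)`.
#' @param P_NF non-enzymatic nucleotide formation from a precursor.
#' @param P_NFR NSR-catalysed nucleotide formation (0 unless NSR modeled).
#' @param P_RL random (surface-mediated) ligation rate.
#' @param P_SP separation of a single base pair; a duplex of r pairs
#'   separates at `P_SP^((r+1)/2)`.
#' @param P_TL non-enzymatic template-directed ligation rate.
#' @param P_TLR REP-catalysed template-directed ligation (0 unless REP
#'   modeled).
#' @param N side of the toroidal grid.
#' @param T_NPB total nucleotide precursors introduced at initialization.
#' @param C_T collision rounds per grid room per step.
#' @param F_CSS chiral-selection factor for surface-mediated synthesis
#'   (0 = complete selection, 1 = none).
#' @param F_CST chiral-selection factor for template-directed synthesis.
#' @param CS_REP catalytic domain sequence of the replicase ribozyme.
#' @param CS_NSR catalytic domain sequence of the nucleotide synthetase
#'   ribozyme.
#'
#' @return An object of class `sim_params` (a named list).
#' @examples
#' p <- sim_params()
#' p$P_SP
#' @export
sim_params <- function(P_AT = 0.5, P_BB = 1e-5, P_CIC = 0.5, P_FP = 0.001,
                       P_MN = 1e-4, P_MPN = 0.002, P_ND = 0.01, P_NDE = 1e-4,
                       P_NF = 0.001, P_NFR = 0, P_RL = 2e-6, P_SP = 0.3,
                       P_TL = 0.002, P_TLR = 0, N = 20, T_NPB = 50000,
                       C_T = 8, F_CSS = 0.5, F_CST = 0.5,
                       CS_REP = "GUUCAG", CS_NSR = "ACUGGC") {
  p <- list(P_AT = P_AT, P_BB = P_BB, P_CIC = P_CIC, P_FP = P_FP,
            P_MN = P_MN, P_MPN = P_MPN, P_ND = P_ND, P_NDE = P_NDE,
            P_NF = P_NF, P_NFR = P_NFR, P_RL = P_RL, P_SP = P_SP,
            P_TL = P_TL, P_TLR = P_TLR, N = as.integer(N),
            T_NPB = as.integer(T_NPB), C_T = as.integer(C_T),
            F_CSS = F_CSS, F_CST = F_CST,
            CS_REP = toupper(CS_REP), CS_NSR = toupper(CS_NSR))
  validate_params(p)
  class(p) <- "sim_params"
  p
}

prob_fields <- c("P_AT", "P_BB", "P_CIC", "P_FP", "P_MN", "P_MPN", "P_ND",
                 "P_NDE", "P_NF", "P_NFR", "P_RL", "P_SP", "P_TL", "P_TLR",
                 "F_CSS", "F_CST")

validate_params <- function(p) {
  for (f in prob_fields) {
    v <- p[[f]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v > 1)
      stop(sprintf("parameter %s must be a single probability in [0, 1]", f),
           call. = FALSE)
  }
  if (p$N < 1L) stop("grid side N must be >= 1", call. = FALSE)
  if (p$T_NPB < 1L) stop("T_NPB must be >= 1", call. = FALSE)
  if (p$C_T < 1L) stop("C_T must be >= 1", call. = FALSE)
  for (f in c("CS_REP", "CS_NSR")) {
    if (!grepl("^[AUCG]+$", p[[f]]))
      stop(sprintf("%s must be a non-empty string over A/U/C/G", f),
           call. = FALSE)
  }
  invisible(p)
}

#' @export
print.sim_params <- function(x, ...) {
  cat("<sim_params>\n")
  for (nm in names(x)) cat(sprintf("  %-7s = %s\n", nm, format(x[[nm]])))
  invisible(x)
}

#' Primer-effect rate ladder
#'
#' Length-dependent extension-rate multipliers modelling the primer effect:
#' a growing chain of 1, 2, 3 or more residues extends with its base rate
#' multiplied by `R1`, `R2`, `R3` or `Rn` respectively. In all published
#' ladders `Rn = R3`, which is the default here.
#'
#' @param R1,R2,R3 multipliers for a monomer, dimer and trimer extender.
#' @param Rn multiplier for extenders longer than three residues.
#' @return An object of class `primer_ladder`.
#' @examples
#' primer_ladder(1, 10, 200) # strong primer effect
#' @export
primer_ladder <- function(R1 = 1, R2 = 1, R3 = 1, Rn = R3) {
  v <- c(R1 = R1, R2 = R2, R3 = R3, Rn = Rn)
  if (any(!is.finite(v)) || any(v < 0))
    stop("ladder multipliers must be finite and >= 0", call. = FALSE)
  structure(as.list(v), class = "primer_ladder")
}

#' @export
print.primer_ladder <- function(x, ...) {
  cat(sprintf("<primer_ladder> R1=%g R2=%g R3=%g Rn=%g\n",
              x$R1, x$R2, x$R3, x$Rn))
  invisible(x)
}

#' Ladder multiplier for a given extender length
#'
#' @param ladder a [primer_ladder()].
#' @param length current residue count of the extending polymer (before
#'   incorporation).
#' @return The applicable multiplier.
#' @export
ladder_multiplier <- function(ladder, length) {
  stopifnot(inherits(ladder, "primer_ladder"), all(length >= 1))
  m <- c(ladder$R1, ladder$R2, ladder$R3, ladder$Rn)
  m[pmin(length, 4L)]
}

ladder_vec <- function(ladder) {
  c(ladder$R1, ladder$R2, ladder$R3, ladder$Rn)
}

#' Write or read a run configuration as a plain-text key=value file
#'
#' All parameters use their published symbols (`P_AT`, `F_CST`, ...). The
#' two primer ladders are stored as comma-separated quadruples and
#' inoculation events as `step:count:length:chirality:sequence` records, one
#' `INOCULATE` line each.
#'
#' @param config a [sim_config()].
#' @param path file path.
#' @return `write_config` returns `path` invisibly; `read_config` returns a
#'   [sim_config()].
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "sim_config"))
  p <- config$params
  lines <- character(0)
  for (nm in names(unclass(p)))
    lines <- c(lines, sprintf("%s=%s", nm, format(p[[nm]], digits = 17)))
  lines <- c(lines,
             sprintf("SURFACE_LADDER=%s",
                     paste(format(ladder_vec(config$surface_ladder),
                                  digits = 17), collapse = ",")),
             sprintf("TEMPLATE_LADDER=%s",
                     paste(format(ladder_vec(config$template_ladder),
                                  digits = 17), collapse = ",")),
             sprintf("STEPS=%d", config$steps),
             sprintf("SEED=%d", config$seed),
             sprintf("RECORD_EVERY=%d", config$record_every),
             sprintf("NO_TERMINATION=%d", as.integer(config$no_termination)))
  for (ino in config$inoculations)
    lines <- c(lines, sprintf("INOCULATE=%d:%d:%d:%s:%s", ino$step,
                              ino$count, ino$length, ino$chirality,
                              ino$sequence))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^\\s*#", lines)]
  kv <- regmatches(lines, regexpr("=", lines), invert = TRUE)
  bad <- lengths(kv) != 2L
  if (any(bad))
    stop(sprintf("malformed config line %d: %s", which(bad)[1],
                 lines[which(bad)[1]]), call. = FALSE)
  keys <- vapply(kv, `[`, "", 1L)
  vals <- vapply(kv, `[`, "", 2L)
  get1 <- function(key, default = NULL) {
    i <- which(keys == key)
    if (length(i) == 0) return(default)
    vals[i[1]]
  }
  pargs <- list()
  for (f in c(prob_fields, "N", "T_NPB", "C_T")) {
    v <- get1(f)
    if (!is.null(v)) pargs[[f]] <- as.numeric(v)
  }
  for (f in c("CS_REP", "CS_NSR")) {
    v <- get1(f)
    if (!is.null(v)) pargs[[f]] <- v
  }
  params <- do.call(sim_params, pargs)
  parse_ladder <- function(key) {
    v <- get1(key)
    if (is.null(v)) return(primer_ladder())
    x <- as.numeric(strsplit(v, ",")[[1]])
    if (length(x) != 4 || any(is.na(x)))
      stop(sprintf("malformed %s in config: %s", key, v), call. = FALSE)
    primer_ladder(x[1], x[2], x[3], x[4])
  }
  inocs <- list()
  for (v in vals[keys == "INOCULATE"]) {
    f <- strsplit(v, ":")[[1]]
    if (length(f) != 5)
      stop(sprintf("malformed INOCULATE record: %s", v), call. = FALSE)
    inocs[[length(inocs) + 1L]] <-
      inoculation(step = as.numeric(f[1]), count = as.integer(f[2]),
                  length = as.integer(f[3]), chirality = f[4],
                  sequence = f[5])
  }
  sim_config(params = params,
             surface_ladder = parse_ladder("SURFACE_LADDER"),
             template_ladder = parse_ladder("TEMPLATE_LADDER"),
             steps = as.numeric(get1("STEPS", "1000")),
             seed = as.integer(get1("SEED", "1")),
             record_every = as.numeric(get1("RECORD_EVERY", "1000")),
             no_termination = as.integer(get1("NO_TERMINATION", "0")) > 0,
             inoculations = inocs)
}
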
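#' Minimum-free-energy folding backends
#'
#' Two interchangeable backends produce a non-crossing secondary structure
#' from a sequence plus optional per-nucleotide pseudo-free-energy terms:
#'
#' * `"reference"` — the built-in dynamic-programming folder
#'   ([fold_reference()]), a simplified energy model carried to full
#'   numerical precision, so the whole pipeline is testable with no
#'   external binary. This is the default.
#' * `"external"` — a thermodynamic nearest-neighbour engine found on the
#'   PATH ([fold_external()]): RNAstructure's `Fold` if present, otherwise
#'   ViennaRNA's `RNAfold`, both driven through their SHAPE pseudo-energy
#'   options (slope/intercept semantics of the Deigan scheme).
#'
#' @param name `"reference"` or `"external"`.
#' @param ... Backend options passed through to the fold function.
#' @return A `fold_backend` object with a `$fold(record, profile, params)`
#'   closure.
#' @export
fold_backend <- function(name = c("reference", "external"), ...) {
  name <- match.arg(name)
  opts <- list(...)
  fold <- if (name == "reference") {
    function(record, profile = NULL, params = NULL)
      do.call(fold_reference, c(list(record, profile = profile), opts))
  } else {
    function(record, profile = NULL, params = energy_params())
      do.call(fold_external, c(list(record, profile = profile, params = params),
                               opts))
  }
  structure(list(name = name, options = opts, fold = fold),
            class = "fold_backend")
}

.PAIR_ENERGY_DEFAULT <- local({
  m <- matrix(Inf, 4, 4, dimnames = list(c("A", "C", "G", "U"),
                                         c("A", "C", "G", "U")))
  m["G", "C"] <- m["C", "G"] <- -3
  m["A", "U"] <- m["U", "A"] <- -2
  m["G", "U"] <- m["U", "G"] <- -1
  m
})

#' Reference dynamic-programming folder
#'
#' Minimizes total energy over all non-crossing structures with the minimum
#' hairpin constraint `j - i > 3` by an O(n^3) interval dynamic program with
#' deterministic traceback (ties prefer the pairing branch, then the
#' smallest partner). The energy model is deliberately simple: per-pair
#' base terms (GC/CG −3, AU/UA −2, GU/UG −1, model units; only canonical
#' pairs allowed) plus, when a pseudo-energy profile is supplied,
#' `dG[i] + dG[j]` added once per formed pair — the per-pair analogue of
#' adding the terms to every stack, which requires a nearest-neighbour
#' decomposition this model does not have. Negative energies stabilize;
#' positive per-nucleotide terms destabilize pairing.
#'
#' @param record An [rna_record()] over A, C, G, U.
#' @param profile Optional [pseudo_energy_profile()] (or bare numeric vector
#'   of per-nucleotide terms, model units).
#' @param pair_energy Optional 4x4 energy matrix (rows/cols A,C,G,U; `Inf`
#'   forbids a pair).
#' @return A `fold_result`: list with `pairs`, `score`, `backend`.
#' @export
fold_reference <- function(record, profile = NULL, pair_energy = NULL) {
  codes <- .seq_codes(record$sequence)
  dg <- numeric(0)
  if (!is.null(profile)) {
    dg <- if (inherits(profile, "pseudo_energy_profile")) profile$dG else profile
    if (length(dg) != length(codes))
      stop("profile length does not match sequence length")
  }
  pe <- if (is.null(pair_energy)) .PAIR_ENERGY_DEFAULT else pair_energy
  res <- fold_reference_cpp(codes, as.numeric(dg), pe, 3L)
  pairs <- res$pairs
  colnames(pairs) <- c("i", "j")
  structure(list(pairs = pairs, score = res$score, backend = "reference"),
            class = "fold_result")
}

.seq_codes <- function(sequence) {
  bases <- strsplit(chartr("T", "U", toupper(sequence)), "")[[1L]]
  codes <- match(bases, c("A", "C", "G", "U")) - 1L
  if (anyNA(codes))
    stop("reference folder requires a pure A/C/G/U sequence; found: ",
         paste(unique(bases[is.na(codes)]), collapse = " "))
  codes
}

#' @export
print.fold_result <- function(x, ...) {
  cat(sprintf("<fold_result> %d pairs, score %.4g (%s backend)\n",
              nrow(x$pairs), x$score, x$backend))
  invisible(x)
}

#' External thermodynamic folding backend
#'
#' Wraps a nearest-neighbour MFE engine found on the PATH. RNAstructure's
#' `Fold` (the engine whose SHAPE slope/intercept scheme the pseudo-energy
#' terms are modelled on) is preferred when installed; otherwise ViennaRNA's
#' `RNAfold`, whose `--shapeMethod=D` option implements the same
#' slope/intercept pseudo-energy rule. When a profile is given it is
#' written as a SHAPE data file and the engine is invoked with the slope
#' `m` and intercept `b` from `params`; with no profile the engine runs as
#' the plain free-energy-minimization baseline. Note stock engines may
#' round uniform offsets to tenths of kcal/mol, which is why the nudge
#' sweep defaults to the reference backend instead.
#'
#' @param record An [rna_record()].
#' @param profile Optional [shape_like_profile()] whose reactivities steer
#'   the fold.
#' @param params [energy_params()] slope/intercept (kcal/mol) applied by
#'   the engine to the SHAPE file.
#' @param exe Path or name of the executable; default: first of
#'   RNAstructure `Fold`, `RNAfold` found on the PATH.
#' @return A `fold_result` with energy in kcal/mol.
#' @export
fold_external <- function(record, profile = NULL, params = energy_params(),
                          exe = NULL) {
  if (is.null(exe)) {
    for (cand in c("Fold", "RNAfold")) {
      if (nzchar(Sys.which(cand))) { exe <- cand; break }
    }
    if (is.null(exe))
      stop("no external folding engine found on the PATH; install ",
           "RNAstructure (`Fold`) or ViennaRNA (`RNAfold`), or pass `exe=`")
  }
  if (!nzchar(Sys.which(exe))) stop("folding executable not found: ", exe)
  tool <- if (grepl("RNAfold", basename(exe))) "rnafold" else "rnastructure"

  td <- tempfile("fold")
  dir.create(td)
  on.exit(unlink(td, recursive = TRUE))
  shape_path <- NULL
  if (!is.null(profile)) {
    alpha <- if (inherits(profile, "shape_like_profile")) profile$alpha else profile
    if (length(alpha) != seq_length(record))
      stop("profile length does not match sequence length")
    shape_path <- file.path(td, "profile.shape")
    write_shape_file(alpha, shape_path)
  }

  if (tool == "rnafold") {
    fa <- file.path(td, "in.fa")
    writeLines(c(paste0(">", record$id), record$sequence), fa)
    args <- c("--noPS", "-i", fa)
    if (!is.null(shape_path))
      args <- c(args, paste0("--shape=", shape_path),
                sprintf("--shapeMethod=Dm%gb%g", params$m, params$b))
    out <- suppressWarnings(system2(exe, args, stdout = TRUE, stderr = TRUE))
    status <- attr(out, "status")
    if (!is.null(status) && status != 0)
      stop("RNAfold failed (exit ", status, "): ", paste(out, collapse = "\n"))
    struct_line <- grep("^[.()\\[\\]{}<>]+\\s+\\(", out, value = TRUE,
                        perl = TRUE)
    if (!length(struct_line))
      stop("could not parse RNAfold output:\n", paste(out, collapse = "\n"))
    toks <- strsplit(trimws(struct_line[[1L]]), "\\s+")[[1L]]
    db <- toks[[1L]]
    energy <- as.numeric(gsub("[()]", "", paste(toks[-1L], collapse = "")))
    pairs <- parse_dotbracket(db)
  } else {
    fa <- file.path(td, "in.fa")
    ct <- file.path(td, "out.ct")
    writeLines(c(paste0(">", record$id), record$sequence), fa)
    args <- c(fa, ct, "-mfe")
    if (!is.null(shape_path))
      args <- c(args, "-sh", shape_path, "-sm", params$m, "-si", params$b)
    out <- suppressWarnings(system2(exe, args, stdout = TRUE, stderr = TRUE))
    status <- attr(out, "status")
    if (!is.null(status) && status != 0)
      stop("Fold failed (exit ", status, "): ", paste(out, collapse = "\n"))
    rec <- read_ct(ct)
    pairs <- rec$pairs
    hdr <- readLines(ct, n = 1L)
    en <- regmatches(hdr, regexpr("-?[0-9.]+", sub("^\\s*[0-9]+", "", hdr)))
    energy <- if (length(en)) as.numeric(en) else NA_real_
  }
  structure(list(pairs = pairs, score = energy, backend = "external"),
            class = "fold_result")
}
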
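#' Fold an RNA/DNA sequence into its minimum-energy nested structure
#'
#' The built-in engine finds the minimum-energy pseudoknot-free structure
#' under a deliberately simple stacking-weighted model: a base pair
#' contributes energy only when stacked on the pair immediately inside it
#' (GC -3, AU -2, GU -1 kcal/mol), every hairpin loop costs +4 kcal/mol, and
#' hairpin loops are at least 3 nt. The empty structure scores 0, so the
#' minimum free energy (MFE) is 0 exactly when no pairing is worthwhile.
#' Bit-compatibility with thermodynamic folders is not claimed; an external
#' folding tool can be plugged in via `engine = "external"` and
#' `external_cmd` (any executable consuming FASTA on standard input and
#' emitting a dot-bracket + "(mfe)" line, e.g. `RNAfold --noPS`).
#'
#' @param sequence nucleotide string (U is normalized to T).
#' @param engine "builtin" or "external".
#' @param external_cmd command line for the external engine.
#' @return object of class `fold_result`: list with `sequence`, `structure`
#'   (dot-bracket), `mfe` (kcal/mol, <= 0) and `pair_table` (integer partner
#'   per position, 0 when unpaired).
#' @export
fold <- function(sequence, engine = c("builtin", "external"),
                 external_cmd = NULL) {
  engine <- match.arg(engine)
  s <- norm_seq(sequence)
  if (grepl("[^ACGT]", s))
    stop("fold: sequence contains non-ACGT characters", call. = FALSE)
  if (engine == "builtin") {
    r <- .fold_engine_cpp(s)
    structure <- r$structure
    mfe <- r$mfe
  } else {
    if (is.null(external_cmd))
      stop("external engine requires external_cmd", call. = FALSE)
    out <- system(external_cmd,
                  input = c(">query", s), intern = TRUE)
    line <- grep("^[.()]+\\s+\\(\\s*-?[0-9.]+\\s*\\)\\s*$", out, value = TRUE)
    if (!length(line))
      stop("external folding engine produced no dot-bracket output",
           call. = FALSE)
    line <- line[length(line)]
    structure <- sub("\\s.*$", "", line)
    mfe <- as.numeric(sub(".*\\(\\s*(-?[0-9.]+)\\s*\\)\\s*$", "\\1", line))
  }
  res <- list(sequence = s, structure = structure, mfe = mfe,
              pair_table = db_pair_table(structure))
  class(res) <- "fold_result"
  res
}

#' @export
print.fold_result <- function(x, ...) {
  cat(x$sequence, "\n", x$structure, " (", format(x$mfe), ")\n", sep = "")
  invisible(x)
}

#' Pair table of a dot-bracket structure
#'
#' @param structure dot-bracket string (nested pairs only).
#' @return integer vector: `pt[i]` is the partner of position `i`, 0 when
#'   unpaired.
#' @export
db_pair_table <- function(structure) {
  ch <- strsplit(structure, "")[[1]]
  pt <- integer(length(ch))
  stack <- integer(0)
  for (i in seq_along(ch)) {
    if (ch[i] == "(") {
      stack <- c(stack, i)
    } else if (ch[i] == ")") {
      if (!length(stack)) stop("unbalanced dot-bracket", call. = FALSE)
      j <- stack[length(stack)]
      stack <- stack[-length(stack)]
      pt[i] <- j; pt[j] <- i
    }
  }
  if (length(stack)) stop("unbalanced dot-bracket", call. = FALSE)
  pt
}

# Hairpin loop interiors of a pair table: list of integer vectors, each the
# unpaired interior of a pair enclosing no other pair.
hairpin_loops <- function(pt) {
  loops <- list()
  for (i in seq_along(pt)) {
    j <- pt[i]
    if (j > i) {
      inside <- if (j - i > 1) (i + 1):(j - 1) else integer(0)
      if (!any(pt[inside] > 0))
        loops[[length(loops) + 1L]] <- inside
    }
  }
  loops
}
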
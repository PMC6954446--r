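#' @title RNA secondary-structure bridge
#' @description Connects mutational signals to RNA secondary structure:
#'   selection and export of unpaired folding constraints (strong
#'   single-strandedness signals), parsing of CT and dot-bracket structure
#'   files produced by an external thermodynamic folding engine, structure
#'   metrics (double-stranded fraction, refolding difference), and a small
#'   deterministic maximum-base-pairing folder so the
#'   constraint -> fold -> metrics path is testable without the external
#'   engine. Thermodynamics itself is never re-implemented; the real engine
#'   is interfaced purely through FASTA/CON/CT files.
#' @name structure
NULL

#' Set of positions constrained to be unpaired during folding
#'
#' @param genome_id reference identifier.
#' @param positions strictly ascending, unique 1-based positions.
#' @param genome_length optional length bound for validation.
#' @return an object of class `ConstraintSet`.
#' @export
constraint_set <- function(genome_id, positions, genome_length = NULL) {
  positions <- as.integer(positions)
  if (length(positions)) {
    if (any(positions < 1L)) stop("constraint positions must be >= 1")
    if (any(diff(positions) <= 0L))
      stop("constraint positions must be strictly ascending and unique")
    if (!is.null(genome_length) && any(positions > genome_length))
      stop("constraint position beyond genome length")
  }
  structure(list(genome_id = genome_id, unpaired_positions = positions),
            class = "ConstraintSet")
}

#' Select unpaired constraints from a single-strandedness signal
#'
#' Picks the strongest DMS-type (A/C mismatch) signals as positions to force
#' unpaired during folding. Two selection rules are available, matching the
#' two ways strong signals are described: a sigma rule (signal exceeding the
#' genome mean by `k` standard deviations, computed over all present
#' coverage-masked signals) and a top-fraction rule (the highest
#' `ceiling(frac * n)` of the background-passing signals). Either way the
#' output is restricted to background-passing positions.
#'
#' @param dms a `SignalProfile` or `ConsensusSignal` from an A/C mismatch
#'   profile pair.
#' @param rule list: `list(type = "sigma", k = 2)` or
#'   `list(type = "top", frac = 0.05)`.
#' @return a [constraint_set()]; empty selections are valid.
#' @export
select_unpaired_constraints <- function(dms, rule = list(type = "sigma", k = 2)) {
  if (inherits(dms, "ConsensusSignal")) {
    values <- dms$mean_signal
    passed <- dms$consistent
    gid <- dms$genome_id
  } else {
    stopifnot(inherits(dms, "SignalProfile"))
    values <- dms$signal
    passed <- dms$passed_background
    gid <- dms$genome_id
  }
  sel <- switch(rule$type,
    sigma = {
      s <- sigma_sites(values, rule$k)
      s[passed[s]]
    },
    top = {
      cand <- which(passed & !is.na(values))
      ntake <- ceiling(rule$frac * length(cand))
      sort(cand[order(-values[cand], cand)][seq_len(ntake)])
    },
    stop("rule$type must be 'sigma' or 'top'"))
  constraint_set(gid, sort(sel), length(values))
}

#' Write a folding-constraint (CON) file
#'
#' Emits the constraint-file dialect understood by thermodynamic folding
#' engines: section headers `DS`, `SS`, `Mod`, `Pairs`, `FMN`, `Forbids` in
#' that order, unpaired positions one per line under `SS:`, single-position
#' sections terminated by `-1` and pair sections by `-1 -1`.
#'
#' @param cs a [constraint_set()].
#' @param path output file.
#' @export
write_constraint_file <- function(cs, path) {
  stopifnot(inherits(cs, "ConstraintSet"))
  lines <- c("DS:", "-1",
             "SS:", as.character(cs$unpaired_positions), "-1",
             "Mod:", "-1",
             "Pairs:", "-1 -1",
             "FMN:", "-1",
             "Forbids:", "-1 -1")
  writeLines(lines, path)
  invisible(path)
}

#' Read a folding-constraint (CON) file
#'
#' Inverse of [write_constraint_file()] for the `SS:` section (the only one
#' this package emits).
#'
#' @param path CON file.
#' @param genome_id identifier for the resulting set (default from filename).
#' @return a [constraint_set()].
#' @export
read_constraint_file <- function(path, genome_id = basename(path)) {
  lines <- trimws(readLines(path))
  ss_at <- which(lines == "SS:")
  if (length(ss_at) != 1L) stop("malformed constraint file: expected one SS: section")
  pos <- integer(0)
  for (ln in lines[-seq_len(ss_at)]) {
    if (ln == "-1" || grepl(":$", ln)) break
    pos <- c(pos, as.integer(ln))
  }
  constraint_set(genome_id, pos)
}

new_structure_model <- function(genome_id, pair) {
  pair <- as.integer(pair)
  nz <- which(pair != 0L)
  if (any(pair[nz] < 1L | pair[nz] > length(pair)))
    stop("pairing partner out of range")
  if (any(pair[nz] == nz))
    stop(sprintf("position %d pairs with itself", nz[which(pair[nz] == nz)[1]]))
  bad <- nz[pair[pair[nz]] != nz]
  if (length(bad))
    stop(sprintf("non-involutive pairing at position %d", bad[1]))
  structure(list(genome_id = genome_id, pair = pair), class = "StructureModel")
}

#' @export
print.StructureModel <- function(x, ...) {
  cat(sprintf("StructureModel '%s': %d nt, %d base pairs (%.1f%% double-stranded)\n",
              x$genome_id, length(x$pair), sum(x$pair != 0L) / 2,
              100 * ds_fraction(x)))
  invisible(x)
}

#' Parse a secondary structure from a CT or dot-bracket file
#'
#' CT files (first line `N [title]`, then per-position
#' `index base prev next pair hist`) may list arbitrary pairs, checked for
#' involution. Dot-bracket files (optionally with a `>` header line and a
#' sequence line; the structure line contains only `.`, `(` and `)`) support
#' nested pairs only.
#'
#' @param path structure file; format is inferred from content unless
#'   `format` is given.
#' @param format `"ct"`, `"dotbracket"` or `"auto"`.
#' @param genome_id identifier for the model (default from the file).
#' @return a `StructureModel` (per-position pairing partner, 0 = unpaired).
#' @export
parse_structure <- function(path, format = c("auto", "ct", "dotbracket"),
                            genome_id = NULL) {
  format <- match.arg(format)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (format == "auto") {
    format <- if (grepl("^\\s*[0-9]+(\\s|$)", lines[1])) "ct" else "dotbracket"
  }
  if (format == "ct") {
    hdr <- strsplit(trimws(lines[1]), "\\s+")[[1]]
    n <- as.integer(hdr[1])
    if (is.na(n) || length(lines) < n + 1L)
      stop("malformed CT file: bad length header")
    pair <- integer(n)
    for (k in seq_len(n)) {
      f <- strsplit(trimws(lines[k + 1L]), "\\s+")[[1]]
      i <- as.integer(f[1])
      j <- as.integer(f[5])
      if (is.na(i) || is.na(j) || i < 1L || i > n)
        stop(sprintf("malformed CT record at line %d", k + 1L))
      pair[i] <- j
    }
    if (is.null(genome_id))
      genome_id <- if (length(hdr) > 1) paste(hdr[-1], collapse = " ") else basename(path)
    new_structure_model(genome_id, pair)
  } else {
    db <- lines[grepl("^[.()]+$", trimws(lines))]
    if (!length(db)) stop("no dot-bracket line found")
    if (is.null(genome_id)) {
      hdr <- lines[startsWith(lines, ">")]
      genome_id <- if (length(hdr)) sub("^>\\s*", "", hdr[1]) else basename(path)
    }
    parse_dotbracket(trimws(db[1]), genome_id)
  }
}

#' Parse a dot-bracket string into a StructureModel
#' @param db string over `.`, `(`, `)`; nested pairs only.
#' @param genome_id identifier for the model.
#' @export
parse_dotbracket <- function(db, genome_id = "structure") {
  ch <- strsplit(db, "", fixed = TRUE)[[1]]
  if (length(ch) && any(!ch %in% c(".", "(", ")")))
    stop("dot-bracket string may contain only '.', '(' and ')'")
  pair <- integer(length(ch))
  stack <- integer(0)
  for (i in seq_along(ch)) {
    if (ch[i] == "(") {
      stack <- c(stack, i)
    } else if (ch[i] == ")") {
      if (!length(stack))
        stop(sprintf("unbalanced ')' at position %d", i))
      j <- stack[length(stack)]
      stack <- stack[-length(stack)]
      pair[i] <- j
      pair[j] <- i
    }
  }
  if (length(stack))
    stop(sprintf("unbalanced '(' at position %d", stack[length(stack)]))
  new_structure_model(genome_id, pair)
}

#' Render a StructureModel as a dot-bracket string
#'
#' Errors on pseudoknotted (non-nested) models, which dot-bracket notation
#' with a single bracket class cannot express.
#'
#' @param s a `StructureModel`.
#' @return character scalar.
#' @export
to_dotbracket <- function(s) {
  stopifnot(inherits(s, "StructureModel"))
  n <- length(s$pair)
  out <- rep(".", n)
  opens <- which(s$pair > seq_len(n))
  for (i in opens) {
    j <- s$pair[i]
    inner <- which(s$pair > 0 & seq_len(n) > i & seq_len(n) < j)
    if (any(s$pair[inner] < i | s$pair[inner] > j))
      stop("structure contains pseudoknots; cannot render as dot-bracket")
    out[i] <- "("
    out[j] <- ")"
  }
  paste(out, collapse = "")
}

#' Write a StructureModel as a CT file
#' @param s a `StructureModel`.
#' @param genome matching [genome()] supplying the sequence (T written as U).
#' @param path output file.
#' @export
write_ct <- function(s, genome, path) {
  stopifnot(inherits(s, "StructureModel"), inherits(genome, "Genome"),
            length(s$pair) == genome_length(genome))
  n <- length(s$pair)
  bases <- chartr("T", "U", genome_bases(genome))
  lines <- c(sprintf("%d %s", n, s$genome_id),
             sprintf("%d %s %d %d %d %d", seq_len(n), bases,
                     seq_len(n) - 1L, c(seq_len(n - 1) + 1L, 0L)[seq_len(n)],
                     s$pair, seq_len(n)))
  writeLines(lines, path)
  invisible(path)
}

#' Double-stranded fraction of a structure
#' @param s a `StructureModel`.
#' @return fraction of positions with a pairing partner, in `[0, 1]`.
#' @export
ds_fraction <- function(s) {
  stopifnot(inherits(s, "StructureModel"))
  if (!length(s$pair)) return(0)
  sum(s$pair != 0L) / length(s$pair)
}

#' Fraction of positions whose pairing status differs between two models
#'
#' Status-level comparison: a position paired in both models counts as
#' unchanged even if its partner differs. This measures how much of the
#' molecule "refolded" between, e.g., unconstrained and constrained
#' predictions.
#'
#' @param a,b `StructureModel`s of equal length.
#' @return fraction in `[0, 1]`.
#' @export
refold_difference <- function(a, b) {
  stopifnot(inherits(a, "StructureModel"), inherits(b, "StructureModel"))
  if (length(a$pair) != length(b$pair))
    stop("structures have different lengths")
  if (!length(a$pair)) return(0)
  mean((a$pair != 0L) != (b$pair != 0L))
}

toy_pairable <- function(x, y) {
  (x == "A" & y == "T") | (x == "T" & y == "A") |
  (x == "C" & y == "G") | (x == "G" & y == "C") |
  (x == "G" & y == "T") | (x == "T" & y == "G")
}

#' Deterministic maximum base-pairing fold (stand-in folder)
#'
#' A Nussinov-style dynamic program maximizing the number of Watson-Crick or
#' GU wobble pairs among nested structures with a minimum hairpin loop of
#' `min_loop` unpaired bases, honouring unpaired constraints. This is NOT a
#' thermodynamic prediction: it exists so the constraint -> fold -> metrics
#' path can be exercised end-to-end without the external folding engine.
#' Among co-optimal structures the traceback is deterministic: scanning from
#' the 5' end, a position is paired whenever an optimal structure allows it,
#' with the smallest admissible partner.
#'
#' @param genome a [genome()] (T treated as U).
#' @param constraints optional [constraint_set()] of positions forced
#'   unpaired.
#' @param min_loop minimum number of unpaired bases in a hairpin loop
#'   (default 3); pairs require `|i - j| > min_loop`.
#' @return a `StructureModel`.
#' @export
toy_fold <- function(genome, constraints = NULL, min_loop = 3L) {
  stopifnot(inherits(genome, "Genome"))
  n <- genome_length(genome)
  bases <- genome_bases(genome)
  blocked <- logical(n)
  if (!is.null(constraints)) {
    stopifnot(inherits(constraints, "ConstraintSet"))
    if (length(constraints$unpaired_positions) &&
        max(constraints$unpaired_positions) > n)
      stop("constraint position beyond genome length")
    blocked[constraints$unpaired_positions] <- TRUE
  }
  pair <- integer(n)
  if (n == 0L) return(new_structure_model(genome$id, pair))
  can <- function(i, j) {
    !blocked[i] && !blocked[j] && (j - i) > min_loop &&
      toy_pairable(bases[i], bases[j])
  }
  N <- matrix(0L, n, n)
  for (span in (min_loop + 1L):max(min_loop + 1L, n - 1L)) {
    if (span > n - 1L) break
    for (i in seq_len(n - span)) {
      j <- i + span
      best <- N[i + 1L, j]
      for (k in (i + min_loop + 1L):j) {
        if (can(i, k)) {
          left <- if (k - 1L >= i + 1L) N[i + 1L, k - 1L] else 0L
          right <- if (k + 1L <= j) N[k + 1L, j] else 0L
          best <- max(best, 1L + left + right)
        }
      }
      N[i, j] <- best
    }
  }
  # traceback: pair i with its smallest admissible partner whenever optimal
  stack <- list(c(1L, n))
  while (length(stack)) {
    iv <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    i <- iv[1]; j <- iv[2]
    while (i < j) {
      if (j - i <= min_loop) break
      paired <- FALSE
      for (k in (i + min_loop + 1L):j) {
        if (can(i, k)) {
          left <- if (k - 1L >= i + 1L) N[i + 1L, k - 1L] else 0L
          right <- if (k + 1L <= j) N[k + 1L, j] else 0L
          if (1L + left + right == N[i, j]) {
            pair[i] <- k
            pair[k] <- i
            if (k + 1L <= j) stack[[length(stack) + 1L]] <- c(k + 1L, j)
            j <- k - 1L
            i <- i + 1L
            paired <- TRUE
            break
          }
        }
      }
      if (!paired) i <- i + 1L
    }
  }
  new_structure_model(genome$id, pair)
}
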
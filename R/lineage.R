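#' @importFrom stats lm coef setNames complete.cases median sd cor rnorm runif uniroot var
#' @importFrom utils read.csv write.csv head tail
NULL

# ---- sequences -------------------------------------------------------------

#' Construct a protein sequence object
#'
#' A thin validated container: an id plus a character vector of one-letter
#' residue codes in 1-based mature-chain numbering (position 1 is the first
#' residue after removal of the initiator Met).
#'
#' @param id character scalar identifier.
#' @param residues character vector of one-letter codes, or a single string.
#' @return An object of class `protein_seq`.
#' @export
protein_seq <- function(id, residues) {
  if (length(residues) == 1L && nchar(residues) > 1L)
    residues <- strsplit(residues, "")[[1]]
  residues <- toupper(residues)
  if (length(residues) == 0L)
    stop("empty sequence")
  bad <- setdiff(unique(residues), AA_ALPHABET)
  if (length(bad))
    stop("non-standard residue code(s): ", paste(bad, collapse = ", "))
  structure(list(id = as.character(id), residues = residues),
            class = "protein_seq")
}

#' @export
print.protein_seq <- function(x, ...) {
  cat(sprintf("<protein_seq> %s (%d aa)\n", x$id, length(x$residues)))
  cat(paste(x$residues, collapse = ""), "\n")
  invisible(x)
}

#' @export
length.protein_seq <- function(x) length(x$residues)

#' Read protein sequences from a FASTA file
#'
#' @param path FASTA file with one or more amino-acid records.
#' @return A list of [protein_seq] objects, named by record id (first token
#'   of the header line).
#' @export
read_fasta_seqs <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  ids <- vapply(strsplit(names(aa), "\\s+"), `[`, "", 1L)
  out <- lapply(seq_along(aa), function(i)
    protein_seq(ids[i], as.character(aa[[i]])))
  names(out) <- ids
  out
}

#' Write protein sequences to a FASTA file
#'
#' @param seqs a [protein_seq] or list of them.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_fasta_seqs <- function(seqs, path) {
  if (inherits(seqs, "protein_seq")) seqs <- list(seqs)
  aa <- Biostrings::AAStringSet(vapply(seqs, function(s)
    paste(s$residues, collapse = ""), ""))
  names(aa) <- vapply(seqs, function(s) s$id, "")
  Biostrings::writeXStringSet(aa, path)
  invisible(path)
}

# ---- substitution events ---------------------------------------------------

#' Parse a compact substitution token
#'
#' Tokens use the conventional `"E27D"` form: original residue, 1-based
#' mature-chain position, replacement residue. No-op substitutions
#' (identical residues) are rejected.
#'
#' @param token character scalar like `"E27D"`.
#' @return A list with elements `from`, `pos`, `to`, class
#'   `substitution_event`.
#' @export
parse_substitution <- function(token) {
  stopifnot(is.character(token), length(token) == 1L)
  m <- regmatches(token, regexec("^([A-Za-z])([0-9]+)([A-Za-z])$", token))[[1]]
  if (length(m) != 4L)
    stop("malformed substitution token: '", token, "'")
  from <- toupper(m[2]); to <- toupper(m[4]); pos <- as.integer(m[3])
  if (!(from %in% AA_ALPHABET) || !(to %in% AA_ALPHABET))
    stop("non-amino-acid letter in token '", token, "'")
  if (pos < 1L)
    stop("position must be >= 1 in token '", token, "'")
  if (from == to)
    stop("no-op substitution '", token, "': identical residues")
  structure(list(from = from, pos = pos, to = to),
            class = "substitution_event")
}

#' Serialize a substitution event back to its compact token
#' @param event a `substitution_event`.
#' @return character scalar, e.g. `"E27D"`.
#' @export
format_substitution <- function(event) {
  paste0(event$from, event$pos, event$to)
}

#' @export
print.substitution_event <- function(x, ...) {
  cat("<substitution_event>", format_substitution(x), "\n")
  invisible(x)
}

as_events <- function(x) {
  if (inherits(x, "substitution_event")) return(list(x))
  lapply(x, function(e)
    if (inherits(e, "substitution_event")) e else parse_substitution(e))
}

#' Apply substitution events to a sequence
#'
#' Forward application replaces `from` residues with `to` residues; reverse
#' application undoes a branch, replacing `to` with `from`. A residue
#' mismatch at any event position is an error (it signals the wrong
#' sequence or a numbering-convention slip), never a silent renumbering.
#'
#' @param seq a [protein_seq].
#' @param events list of `substitution_event`s or compact tokens.
#' @param direction `"forward"` or `"reverse"`.
#' @param id id for the returned sequence (default: input id).
#' @return A new [protein_seq].
#' @export
apply_events <- function(seq, events, direction = c("forward", "reverse"),
                         id = seq$id) {
  direction <- match.arg(direction)
  events <- as_events(events)
  res <- seq$residues
  n <- length(res)
  for (e in events) {
    if (e$pos > n)
      stop("event ", format_substitution(e), " beyond sequence length ", n)
    expected <- if (direction == "forward") e$from else e$to
    replacement <- if (direction == "forward") e$to else e$from
    if (res[e$pos] != expected)
      stop("residue mismatch for event ", format_substitution(e),
           " (", direction, "): expected ", expected, " at position ",
           e$pos, ", found ", res[e$pos])
    res[e$pos] <- replacement
  }
  protein_seq(id, res)
}

# ---- lineage ---------------------------------------------------------------

#' Build the myoglobin lineage from the packaged sequence and event lists
#'
#' Reconstructs the ancestral sequence chain by reverse-applying the curated
#' per-branch substitution lists, starting from the packaged extant
#' sperm-whale mature sequence. The main path is
#' aMbWp -> aMbWb -> swMb (7 and 10 events); the alternative whale-ancestor
#' reconstruction aMbWb' is derived from aMbWb as a two-site variant
#' (positions 1 and 15). Ancestors are always derived, never hard-coded.
#'
#' @param fasta path to the extant-sequence FASTA (default: packaged swMb).
#' @param events_json path to the branch/variant event lists (default:
#'   packaged curated lists).
#' @return An object of class `mb_lineage` with elements `sequences` (named
#'   list of [protein_seq]), `path` (ordered main-path ids), `branches`
#'   (named list of event lists `"parent->child"`), `variants`.
#' @export
mb_lineage <- function(fasta = system.file("extdata", "swMb_mature.fasta",
                                           package = "paleomb"),
                       events_json = system.file("extdata",
                                                 "lineage_events.json",
                                                 package = "paleomb")) {
  seqs <- read_fasta_seqs(fasta)
  spec <- jsonlite::fromJSON(events_json, simplifyVector = FALSE)
  path <- unlist(spec$path)
  tip <- path[length(path)]
  if (!tip %in% names(seqs))
    stop("tip sequence '", tip, "' not found in FASTA")
  sequences <- list()
  sequences[[tip]] <- seqs[[tip]]
  branches <- list()
  # walk the branches tip-to-root, reverse-applying each event list
  for (br in rev(spec$branches)) {
    child <- br$child; parent <- br$parent
    ev <- as_events(unlist(br$events))
    branches[[paste0(parent, "->", child)]] <- ev
    if (is.null(sequences[[child]]))
      stop("branch order broken: child '", child, "' not yet reconstructed")
    sequences[[parent]] <-
      apply_events(sequences[[child]], ev, "reverse", id = parent)
  }
  variants <- list()
  for (v in spec$variants) {
    ev <- as_events(unlist(v$events))
    variants[[v$id]] <- list(of = v$of, events = ev)
    sequences[[v$id]] <-
      apply_events(sequences[[v$of]], ev, "reverse", id = v$id)
  }
  structure(list(sequences = sequences, path = path,
                 branches = branches, variants = variants),
            class = "mb_lineage")
}

#' @export
print.mb_lineage <- function(x, ...) {
  cat("<mb_lineage>", paste(x$path, collapse = " -> "), "\n")
  for (nm in names(x$branches))
    cat(sprintf("  %s: %d events\n", nm, length(x$branches[[nm]])))
  for (nm in names(x$variants))
    cat(sprintf("  variant %s of %s: %d events\n", nm, x$variants[[nm]]$of,
                length(x$variants[[nm]]$events)))
  invisible(x)
}

#' Count substitution events along the main lineage path
#'
#' Sums the branch event counts between two nodes of the main path. Events
#' are counted, not site differences: a site substituted and later reverted
#' contributes two events. Variant nodes are not on the main path and are
#' rejected.
#'
#' @param lineage an [mb_lineage].
#' @param from,to node ids; `from` must be ancestral to (or equal to) `to`.
#' @return integer event count.
#' @export
count_events <- function(lineage, from, to) {
  path <- lineage$path
  i <- match(from, path); j <- match(to, path)
  if (is.na(i) || is.na(j))
    stop("'", if (is.na(i)) from else to, "' is not on the main lineage path")
  if (i > j)
    stop("'", from, "' is not ancestral to '", to, "'")
  if (i == j) return(0L)
  n <- 0L
  for (k in seq(i, j - 1L)) {
    key <- paste0(path[k], "->", path[k + 1L])
    n <- n + length(lineage$branches[[key]])
  }
  n
}

#' Count differing sites between two equal-length sequences
#'
#' @param a,b [protein_seq] objects of equal length.
#' @return integer number of positions with differing residues.
#' @export
pairwise_differences <- function(a, b) {
  if (length(a$residues) != length(b$residues))
    stop("sequence length mismatch: ", length(a$residues), " vs ",
         length(b$residues))
  sum(a$residues != b$residues)
}

# ---- sequence properties ---------------------------------------------------

#' Average molecular mass of a protein chain
#'
#' Sum of average residue masses plus one water.
#'
#' @param seq a [protein_seq].
#' @return mass in Da.
#' @export
molecular_mass <- function(seq) {
  sum(RESIDUE_MASS[seq$residues]) + WATER_MASS
}

#' Formal net charge of a protein at neutral pH
#'
#' Formal counting, not a titration: +1 per Lys and Arg, `his_charge` per
#' His, +1 for the N-terminal amine; -1 per Asp and Glu and -1 for the
#' C-terminal carboxyl; optionally -2 for the two heme propionates of the
#' holo-protein. Defaults (His neutral, termini included, heme excluded)
#' follow the usual formal-charge bookkeeping for the apo chain.
#'
#' @param seq a [protein_seq].
#' @param his_charge 0 (default) or +1 charge assigned to each His.
#' @param include_heme if `TRUE`, subtract 2 for the heme propionates.
#' @return net charge in elementary charges.
#' @export
formal_net_charge <- function(seq, his_charge = 0, include_heme = FALSE) {
  r <- seq$residues
  pos <- sum(r == "K") + sum(r == "R") + his_charge * sum(r == "H") + 1
  neg <- sum(r == "D") + sum(r == "E") + 1
  pos - neg - if (include_heme) 2 else 0
}

# titration charge at a given pH under Henderson-Hasselbalch
titration_charge <- function(counts, pka, pH) {
  z <- 0
  for (g in names(pka)) {
    n <- counts[[g]]
    if (is.null(n) || n == 0) next
    if (g %in% c("nterm", POSITIVE_SIDE_CHAINS)) {
      z <- z + n / (1 + 10^(pH - pka[[g]]))
    } else {
      z <- z - n / (1 + 10^(pka[[g]] - pH))
    }
  }
  z
}

#' Isoelectric point by bisection of the titration curve
#'
#' Finds the pH in \[0, 14\] at which the Henderson-Hasselbalch titration
#' charge crosses zero, by bisection to a pH tolerance of 1e-4. The pKa
#' table used is recorded in the result for provenance.
#'
#' @param seq a [protein_seq], or `NULL` when `counts` is given directly.
#' @param pka_set name of a packaged table in [PKA_SETS], or a named numeric
#'   vector of pKa values (`nterm`, `cterm` and side-chain letters).
#' @param counts optional named list of group counts overriding the
#'   sequence-derived counts (used for reduced titration models).
#' @param tol bisection tolerance on pH.
#' @return list with `pI`, `charge_at_pI`, `pka_set` (name or "custom").
#' @export
isoelectric_point <- function(seq = NULL, pka_set = "emboss", counts = NULL,
                              tol = 1e-4) {
  if (is.character(pka_set)) {
    pka_name <- pka_set
    pka <- PKA_SETS[[pka_set]]
    if (is.null(pka)) stop("unknown pKa set '", pka_set, "'")
  } else {
    pka_name <- "custom"
    pka <- pka_set
  }
  if (is.null(counts)) {
    if (is.null(seq)) stop("either a sequence or explicit counts required")
    r <- seq$residues
    counts <- c(list(nterm = 1, cterm = 1),
                as.list(table(factor(r, levels = AA_ALPHABET))))
  }
  f <- function(pH) titration_charge(counts, pka, pH)
  lo <- 0; hi <- 14
  flo <- f(lo); fhi <- f(hi)
  if (flo < 0 || fhi > 0)
    stop("titration charge has no sign change on [0, 14]")
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) lo <- mid else hi <- mid
  }
  pI <- (lo + hi) / 2
  list(pI = pI, charge_at_pI = f(pI), pka_set = pka_name)
}

#' Pairwise evolutionary distance between two sequences
#'
#' `model = "p"` gives the raw proportion of differing sites;
#' `model = "poisson"` applies the Poisson multiple-hit correction
#' d = -ln(1 - p). The published distances come from a full phylogenetic
#' tree over a large globin alignment; per-pair Poisson distance preserves
#' the lineage ordering but not the absolute scale.
#'
#' @param a,b equal-length [protein_seq] objects.
#' @param model `"poisson"` (default) or `"p"`.
#' @return distance in substitutions per site.
#' @export
evolutionary_distance <- function(a, b, model = c("poisson", "p")) {
  model <- match.arg(model)
  p <- pairwise_differences(a, b) / length(a$residues)
  if (model == "p") return(p)
  if (p >= 1) stop("p-distance >= 1: Poisson correction undefined")
  -log(1 - p)
}

#' Per-taxon sequence property table for a lineage
#'
#' Computes molecular mass, formal net charge, isoelectric point and
#' Poisson-corrected evolutionary distance from the extant tip for every
#' taxon in the lineage.
#'
#' @param lineage an [mb_lineage].
#' @param pka_set passed to [isoelectric_point()].
#' @param his_charge,include_heme passed to [formal_net_charge()].
#' @return data.frame with one row per taxon: `taxon`, `Mr`, `Z`, `pI`, `d`,
#'   ordered by decreasing distance from the tip.
#' @export
sequence_properties <- function(lineage, pka_set = "emboss",
                                his_charge = 0, include_heme = FALSE) {
  tip <- lineage$path[length(lineage$path)]
  tip_seq <- lineage$sequences[[tip]]
  rows <- lapply(names(lineage$sequences), function(id) {
    s <- lineage$sequences[[id]]
    data.frame(
      taxon = id,
      Mr = molecular_mass(s),
      Z = formal_net_charge(s, his_charge, include_heme),
      pI = isoelectric_point(s, pka_set)$pI,
      d = evolutionary_distance(tip_seq, s, "poisson"),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$d), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "pka_set") <- if (is.character(pka_set)) pka_set else "custom"
  out
}
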
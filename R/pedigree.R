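#' Construct a validated, topologically sorted pedigree
#'
#' Builds a pedigree object from animal/sire/dam identifier vectors. Animals
#' appearing only as parents are inserted as founders. Records are reordered
#' (stable Kahn topological sort, input order as tie-break) so that every
#' parent precedes its offspring; inbreeding coefficients and
#' Mendelian-sampling variances are computed by the Meuwissen-Luo recursion.
#'
#' @param id character vector of animal identifiers (unique).
#' @param sire,dam character vectors of parent identifiers; `NA` marks an
#'   unknown parent. Unknown parents contribute no relationship and are
#'   treated as unrelated founders (no unknown-parent groups).
#' @return An object of class `pedigree`: a data.frame with columns
#'   `id`, `sire`, `dam` (character, `NA` for unknown), `sire_idx`,
#'   `dam_idx` (integer positions, `NA` for unknown), `F` (inbreeding
#'   coefficient) and `D` (Mendelian-sampling variance as a fraction of the
#'   additive variance).
#' @examples
#' ped <- pedigree(c("A", "B", "C"), c(NA, NA, "A"), c(NA, NA, "B"))
#' ped$F
#' @export
pedigree <- function(id, sire, dam) {
  id <- as.character(id); sire <- as.character(sire); dam <- as.character(dam)
  stopifnot(length(id) == length(sire), length(id) == length(dam))
  if (anyNA(id)) stop("animal identifiers must not be missing")
  if (anyDuplicated(id)) {
    stop("duplicate animal rows: ", paste(unique(id[duplicated(id)]), collapse = ", "))
  }
  if (any(!is.na(sire) & sire == id) || any(!is.na(dam) & dam == id))
    stop("cycle detected in pedigree involving animal ",
         id[which(!is.na(sire) & sire == id | !is.na(dam) & dam == id)[1]])
  both <- intersect(stats::na.omit(unique(sire)), stats::na.omit(unique(dam)))
  if (length(both) > 0)
    stop("animal listed as both sire and dam: ", paste(both, collapse = ", "))

  # insert parents with no own row as founders, preserving first appearance
  parents <- unique(c(sire[!is.na(sire)], dam[!is.na(dam)]))
  missing <- setdiff(parents, id)
  if (length(missing) > 0) {
    id <- c(missing, id)
    sire <- c(rep(NA_character_, length(missing)), sire)
    dam <- c(rep(NA_character_, length(missing)), dam)
  }

  ord <- kahn_order(id, sire, dam)
  id <- id[ord]; sire <- sire[ord]; dam <- dam[ord]
  sire_idx <- match(sire, id)
  dam_idx <- match(dam, id)

  ml <- inbreeding_ml(ifelse(is.na(sire_idx), -1L, sire_idx - 1L),
                      ifelse(is.na(dam_idx), -1L, dam_idx - 1L))
  out <- data.frame(id = id, sire = sire, dam = dam,
                    sire_idx = sire_idx, dam_idx = dam_idx,
                    F = ml$F, D = ml$D,
                    stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("pedigree", "data.frame")
  out
}

# Stable Kahn topological sort; ties broken by input position so the output
# ordering is reproducible. Errors with an animal on a cycle if one exists.
kahn_order <- function(id, sire, dam) {
  n <- length(id)
  sire_idx <- match(sire, id)
  dam_idx <- match(dam, id)
  indeg <- (!is.na(sire_idx)) + (!is.na(dam_idx))
  # children adjacency
  kids <- vector("list", n)
  for (i in seq_len(n)) {
    if (!is.na(sire_idx[i])) kids[[sire_idx[i]]] <- c(kids[[sire_idx[i]]], i)
    if (!is.na(dam_idx[i])) kids[[dam_idx[i]]] <- c(kids[[dam_idx[i]]], i)
  }
  ready <- which(indeg == 0)           # ascending input order
  out <- integer(0)
  while (length(ready) > 0) {
    v <- ready[1]; ready <- ready[-1]
    out <- c(out, v)
    for (k in kids[[v]]) {
      indeg[k] <- indeg[k] - 1L
      if (indeg[k] == 0L) {
        pos <- findInterval(k, ready)
        ready <- append(ready, k, after = pos)
      }
    }
  }
  if (length(out) < n) {
    leftover <- setdiff(seq_len(n), out)
    stop("cycle detected in pedigree involving animal ", id[leftover[1]])
  }
  out
}

#' Read a pedigree file
#'
#' Reads a delimited text file (comma or tab, autodetected) with at least
#' three columns: animal, sire, dam. Configurable codes mark unknown
#' parents. Animals appearing only as parents are inserted as founders, and
#' the result is topologically sorted (see [pedigree()]).
#'
#' @param path path to the pedigree file.
#' @param unknown_codes character vector of strings coding an unknown
#'   parent; default `c("0", "NA", "")`.
#' @param header logical, does the file have a header row? Default `TRUE`.
#' @return A [pedigree()] object.
#' @export
read_pedigree <- function(path, unknown_codes = c("0", "NA", ""), header = TRUE) {
  sep <- detect_sep(path)
  df <- utils::read.table(path, sep = sep, header = header,
                          colClasses = "character", stringsAsFactors = FALSE,
                          na.strings = character(0), quote = "\"",
                          comment.char = "")
  if (ncol(df) < 3) stop("pedigree file needs >= 3 columns (animal, sire, dam)")
  s <- df[[2]]; d <- df[[3]]
  s[s %in% unknown_codes] <- NA_character_
  d[d %in% unknown_codes] <- NA_character_
  pedigree(df[[1]], s, d)
}

detect_sep <- function(path) {
  line <- readLines(path, n = 1L)
  if (grepl("\t", line)) "\t" else if (grepl(",", line)) "," else ""
}

#' @export
print.pedigree <- function(x, ...) {
  cat("Pedigree with", nrow(x), "animals;",
      sum(is.na(x$sire_idx) & is.na(x$dam_idx)), "founders; mean F =",
      signif(mean(x$F), 4), "\n")
  invisible(x)
}

#' Truncate a pedigree to a fixed number of ancestral generations
#'
#' Keeps, for a set of focal animals, their ancestors up to `n_generations`
#' back; parent links beyond the horizon are set to unknown. Useful when
#' the recording system only traces each animal a fixed number of
#' generations.
#'
#' @param ped a [pedigree()] object.
#' @param focal_ids identifiers of the focal animals (default: all).
#' @param n_generations number of ancestral generations to retain.
#' @return A new [pedigree()] object.
#' @export
truncate_pedigree <- function(ped, focal_ids = ped$id, n_generations = 3L) {
  stopifnot(inherits(ped, "pedigree"), n_generations >= 0)
  keep_depth <- rep(-1L, nrow(ped))
  frontier <- match(focal_ids, ped$id)
  if (anyNA(frontier)) stop("unknown focal ids")
  keep_depth[frontier] <- 0L
  for (g in seq_len(n_generations)) {
    frontier <- unique(stats::na.omit(c(ped$sire_idx[frontier], ped$dam_idx[frontier])))
    if (length(frontier) == 0) break
    fresh <- frontier[keep_depth[frontier] < 0]
    keep_depth[fresh] <- g
  }
  keep <- keep_depth >= 0
  id <- ped$id[keep]
  sire <- ifelse(keep_depth[keep] < n_generations, ped$sire[keep], NA_character_)
  dam <- ifelse(keep_depth[keep] < n_generations, ped$dam[keep], NA_character_)
  sire[!(sire %in% id)] <- NA_character_
  dam[!(dam %in% id)] <- NA_character_
  pedigree(id, sire, dam)
}
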
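## Pedigree container: a data.frame in topological order (parents before
## offspring) with character ids, NA-coded unknown parents, and an optional
## environment label column (NA = the animal's own singleton environment).

unknown_codes <- c("0", "", "na", ".")

normalize_parent <- function(x) {
  x <- as.character(x)
  x[is.na(x) | tolower(trimws(x)) %in% unknown_codes] <- NA_character_
  trimws(x)
}

#' Build a validated pedigree
#'
#' Constructs a pedigree object from parallel vectors of animal, sire and dam
#' identifiers.  Unknown parents may be encoded as `NA`, `0`, `""`, `"."` or
#' `"NA"` (case-insensitive).  Records are reordered so that every parent
#' precedes its offspring; a cycle (an animal that is its own ancestor) is a
#' fatal error naming the offending animals.  Every named parent must itself
#' have a record: no phantom parents are created.
#'
#' Environment labels partition the animals.  A label carried by a single
#' animal, or an `NA` label, means the animal lives in its own environment,
#' distinct from every other.
#'
#' @param id character vector of unique animal identifiers.
#' @param sire,dam parent identifiers (same length as `id`); unknowns as above.
#' @param env optional environment labels; `NA` for singleton environments.
#' @param extra optional `data.frame` of additional per-animal columns
#'   (phenotypes, fixed effects, design tags); reordered along with the
#'   records.
#' @return A `trans_ped` object: a `data.frame` with columns `id`, `sire`,
#'   `dam`, `env`, integer parent indices `sire_idx`/`dam_idx`, and any
#'   extra columns, in topological order.
#' @examples
#' ped <- pedigree(id = c("o", "s", "d"), sire = c("s", NA, NA),
#'                 dam = c("d", NA, NA))
#' ped$id  # reordered: founders first
#' @export
pedigree <- function(id, sire = NULL, dam = NULL, env = NULL, extra = NULL) {
  id <- trimws(as.character(id))
  n <- length(id)
  if (n == 0L) stop("empty pedigree")
  if (anyDuplicated(id)) {
    stop("duplicated animal ids: ", paste(unique(id[duplicated(id)]), collapse = ", "))
  }
  sire <- if (is.null(sire)) rep(NA_character_, n) else normalize_parent(sire)
  dam <- if (is.null(dam)) rep(NA_character_, n) else normalize_parent(dam)
  for (p in list(sire, dam)) {
    missing_parent <- setdiff(p[!is.na(p)], id)
    if (length(missing_parent)) {
      stop("parent id(s) absent from the pedigree: ",
           paste(unique(missing_parent), collapse = ", "))
    }
  }
  env <- if (is.null(env)) rep(NA_character_, n) else as.character(env)

  ord <- toposort_pedigree(id, sire, dam)
  df <- data.frame(id = id, sire = sire, dam = dam, env = env,
                   stringsAsFactors = FALSE)
  if (!is.null(extra)) {
    extra <- as.data.frame(extra)
    stopifnot(nrow(extra) == n)
    df <- cbind(df, extra[setdiff(names(extra), names(df))])
  }
  df <- df[ord, , drop = FALSE]
  rownames(df) <- NULL
  df$sire_idx <- match(df$sire, df$id)
  df$dam_idx <- match(df$dam, df$id)
  class(df) <- c("trans_ped", "data.frame")
  df
}

## Kahn's algorithm; returns an ordering with parents before offspring or
## fails naming the animals on a cycle.
toposort_pedigree <- function(id, sire, dam) {
  n <- length(id)
  si <- match(sire, id)
  di <- match(dam, id)
  n_pending <- (!is.na(si)) + (!is.na(di))
  children <- vector("list", n)
  for (i in seq_len(n)) {
    for (p in c(si[i], di[i])) {
      if (!is.na(p)) children[[p]] <- c(children[[p]], i)
    }
  }
  queue <- which(n_pending == 0L)
  ord <- integer(0)
  while (length(queue)) {
    i <- queue[1L]
    queue <- queue[-1L]
    ord <- c(ord, i)
    for (ch in children[[i]]) {
      n_pending[ch] <- n_pending[ch] - 1L
      if (n_pending[ch] == 0L) queue <- c(queue, ch)
    }
  }
  if (length(ord) < n) {
    stuck <- setdiff(seq_len(n), ord)
    stop("pedigree cycle detected (animal its own ancestor) involving: ",
         paste(id[stuck], collapse = ", "))
  }
  ord
}

#' Read a pedigree (and attached phenotype columns) from a delimited file
#'
#' Reads a CSV or whitespace-delimited text file with a header line and
#' returns a validated, topologically ordered [pedigree()].  Columns other
#' than the id/parent/environment columns (phenotype, fixed effects, design
#' tags) are preserved and reordered with the records.
#'
#' @param path path to the file.  The delimiter is auto-detected (comma if
#'   the header contains one, otherwise whitespace) unless `sep` is given.
#' @param columns named character vector remapping file column names; names
#'   used: `animal`, `sire`, `dam`, `environment` (the last one optional in
#'   the file).
#' @param sep field separator, or `NULL` to auto-detect.
#' @return A `trans_ped` object (see [pedigree()]).
#' @export
read_pedigree <- function(path,
                          columns = c(animal = "animal", sire = "sire",
                                      dam = "dam", environment = "environment"),
                          sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(sep)) {
    header <- readLines(path, n = 1L)
    sep <- if (grepl(",", header, fixed = TRUE)) "," else ""
  }
  raw <- read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE,
                    check.names = FALSE, colClasses = "character")
  defaults <- c(animal = "animal", sire = "sire", dam = "dam",
                environment = "environment")
  defaults[names(columns)] <- columns
  columns <- defaults
  for (role in c("animal", "sire", "dam")) {
    if (!columns[[role]] %in% names(raw)) {
      stop("column '", columns[[role]], "' (", role, ") not found in ", path)
    }
  }
  env <- if (columns[["environment"]] %in% names(raw)) {
    raw[[columns[["environment"]]]]
  } else {
    NULL
  }
  used <- intersect(unname(columns), names(raw))
  extra <- raw[setdiff(names(raw), used)]
  ## numeric- and logical-looking extras (phenotypes, covariates, design
  ## flags) back to their natural types
  for (nm in names(extra)) {
    filled <- !is.na(extra[[nm]]) & trimws(extra[[nm]]) != ""
    if (all(toupper(trimws(extra[[nm]][filled])) %in% c("TRUE", "FALSE"))) {
      extra[[nm]] <- as.logical(toupper(trimws(extra[[nm]])))
      next
    }
    v <- suppressWarnings(as.numeric(extra[[nm]]))
    if (!anyNA(v[filled])) extra[[nm]] <- v
  }
  pedigree(id = raw[[columns[["animal"]]]],
           sire = raw[[columns[["sire"]]]],
           dam = raw[[columns[["dam"]]]],
           env = env,
           extra = if (ncol(extra)) extra else NULL)
}

#' @method print trans_ped
#' @export
print.trans_ped <- function(x, ...) {
  known <- sum(!is.na(x$sire_idx) | !is.na(x$dam_idx))
  shared <- env_blocks(x)
  cat("Pedigree with", nrow(x), "animals (",
      nrow(x) - known, "founder-like records ),",
      length(shared), "shared environment(s)\n")
  NextMethod()
  invisible(x)
}

## shared-environment blocks: labels held by >= 2 animals.  Singleton labels
## and NA labels denote own-environment animals and yield no block.
env_blocks <- function(ped) {
  env <- ped$env
  keep <- !is.na(env)
  if (!any(keep)) return(list())
  tab <- table(env[keep])
  labels <- names(tab[tab >= 2L])
  lapply(labels, function(lab) {
    members <- which(!is.na(env) & env == lab)
    list(label = lab, members = members, m = length(members))
  })
}

## per-animal parental-knowledge status used by the delta rules
parent_known <- function(ped) {
  list(sire = !is.na(ped$sire_idx), dam = !is.na(ped$dam_idx))
}
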
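#' Named gene sets over a ranked universe
#'
#' @param sets Named list of character vectors of gene identifiers.
#' @param universe Character vector of all gene identifiers under analysis.
#'   Set members outside the universe are dropped (with a message giving the
#'   count); a set left empty by the intersection is an error.
#' @return A list of class `gene_set_collection` with elements `sets`,
#'   `universe` and `n_dropped` (per-set dropped-member counts).
#' @export
gene_set_collection <- function(sets, universe) {
  if (!length(sets) || is.null(names(sets)) || any(!nzchar(names(sets))))
    stopf("'sets' must be a nonempty named list")
  if (anyDuplicated(names(sets))) stopf("set names must be unique")
  universe <- as.character(universe)
  if (!length(universe) || anyDuplicated(universe))
    stopf("'universe' must be nonempty with unique identifiers")
  n_dropped <- integer(length(sets))
  names(n_dropped) <- names(sets)
  for (nm in names(sets)) {
    members <- unique(as.character(sets[[nm]]))
    keep <- members %in% universe
    n_dropped[[nm]] <- sum(!keep)
    if (n_dropped[[nm]] > 0L)
      message(sprintf("gene_set_collection: set '%s': dropped %d member(s) outside the universe",
                      nm, n_dropped[[nm]]))
    if (!any(keep))
      stopf("set '%s' has no members in the universe", nm)
    sets[[nm]] <- members[keep]
  }
  structure(list(sets = sets, universe = universe, n_dropped = n_dropped),
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("gene_set_collection: %d sets over %d genes\n",
              length(x$sets), length(x$universe)))
  for (nm in names(x$sets))
    cat(sprintf("  %s: %d members\n", nm, length(x$sets[[nm]])))
  invisible(x)
}

#' Read / write gene sets in GMT format
#'
#' GMT is the tab-separated gene-set exchange format: one set per line as
#' `name <TAB> description <TAB> member1 <TAB> member2 ...`.
#'
#' @param path File path.
#' @param sets Named list of identifier vectors (or a
#'   `gene_set_collection`, whose `sets` element is used).
#' @param descriptions Optional character vector of per-set descriptions.
#' @return `read_gmt` returns a named list of identifier vectors.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stopf("GMT file not found: %s", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stopf("GMT file is empty: %s", path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 3L)
  if (length(bad))
    stopf("GMT line %d has fewer than 3 fields", bad[1])
  sets <- lapply(parts, function(p) p[-(1:2)])
  names(sets) <- vapply(parts, `[[`, character(1), 1L)
  if (anyDuplicated(names(sets))) stopf("duplicate set names in %s", path)
  sets
}

#' @rdname read_gmt
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (inherits(sets, "gene_set_collection")) sets <- sets$sets
  if (is.null(descriptions)) descriptions <- rep("na", length(sets))
  lines <- vapply(seq_along(sets), function(i)
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t"),
    character(1))
  writeLines(lines, path)
  invisible(path)
}
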
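#' Population map: sample -> species/group assignment
#'
#' @param assignments named character vector mapping sample id to group
#'   label (names are sample ids).
#' @return An object of class `pop_map` with fields `assignments` (named
#'   character vector) and `groups` (list label -> ordered sample ids).
#'   Groups partition the sample set: every sample belongs to exactly
#'   one group.
#' @export
pop_map <- function(assignments) {
  if (is.null(names(assignments)) || anyNA(names(assignments)) ||
      any(names(assignments) == "")) {
    stop("assignments must be a named vector (sample -> group)")
  }
  if (anyDuplicated(names(assignments))) {
    stop("each sample must be assigned to exactly one group")
  }
  assignments <- vapply(assignments, as.character, character(1))
  groups <- split(names(assignments), assignments)
  # keep first-appearance order of group labels
  groups <- groups[unique(unname(assignments))]
  structure(list(assignments = assignments, groups = groups),
            class = "pop_map")
}

#' @export
print.pop_map <- function(x, ...) {
  cat(sprintf("pop_map: %d samples in %d groups\n",
              length(x$assignments), length(x$groups)))
  sizes <- vapply(x$groups, length, integer(1))
  cat(paste(sprintf("  %s (%d)", names(sizes), sizes), collapse = "\n"), "\n")
  invisible(x)
}

#' Read a population map TSV
#'
#' Format: `sample<TAB>group`, no header; lines starting with `#` are
#' comments.
#'
#' @param path file path.
#' @return a [pop_map()].
#' @export
read_popmap <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(parts, length, integer(1)) < 2L)
  if (length(bad) > 0) {
    stop("malformed population map line ", bad[1], ": expected sample<TAB>group")
  }
  pop_map(stats::setNames(vapply(parts, `[[`, character(1), 2L),
                          vapply(parts, `[[`, character(1), 1L)))
}

#' Write a population map TSV
#' @param pm a [pop_map()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_popmap <- function(pm, path) {
  writeLines(paste(names(pm$assignments), pm$assignments, sep = "\t"), path)
  invisible(path)
}

#' Samples belonging to one or more groups
#' @param pm a [pop_map()].
#' @param groups character vector of group labels.
#' @return character vector of sample ids, in map order.
#' @export
group_samples <- function(pm, groups) {
  unknown <- setdiff(groups, names(pm$groups))
  if (length(unknown) > 0) {
    stop("unknown group(s): ", paste(unknown, collapse = ", "))
  }
  unlist(pm$groups[groups], use.names = FALSE)
}

# column indices of a group's samples within a geno_matrix
.group_cols <- function(gm, pm, groups) {
  ids <- group_samples(pm, groups)
  j <- match(ids, gm$samples)
  if (anyNA(j)) {
    stop("sample(s) in population map absent from genotypes: ",
         paste(ids[is.na(j)], collapse = ", "))
  }
  j
}
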
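#' Read a chunklengths matrix
#'
#' Reads the whitespace-delimited copying-vector table produced by summing a
#' chromosome-painting run over chromosomes: a header row whose first token
#' names the recipient column followed by one label per donor cluster, then
#' one row per recipient holding the total genome length (in cM) copied from
#' each donor.
#'
#' @param path Path to a chunklengths file.
#' @return A tibble with a character `recipient` column followed by one
#'   numeric column per donor cluster, in file order. The row sum of the
#'   donor columns is the recipient's total copied length `C`.
#' @seealso [write_chunklengths()], [copying_fractions()]
#' @export
read_chunklengths <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("chunklengths file not found: ", path))
  }
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 1L) abort("chunklengths file is empty")
  toks <- strsplit(trimws(lines), "[ \t]+")
  header <- toks[[1L]]
  if (length(header) < 2L) abort("chunklengths header needs at least one donor label")
  donors <- header[-1L]
  if (anyDuplicated(donors)) {
    abort(paste0("duplicate donor label in header: ",
                 paste(unique(donors[duplicated(donors)]), collapse = ", ")))
  }
  d <- length(donors)
  body <- toks[-1L]
  for (i in seq_along(body)) {
    if (length(body[[i]]) != d + 1L) {
      abort(sprintf("ragged row at line %d: expected %d fields, found %d",
                    i + 1L, d + 1L, length(body[[i]])))
    }
  }
  rec <- vapply(body, `[[`, character(1), 1L)
  vals <- matrix(NA_real_, nrow = length(body), ncol = d)
  for (i in seq_along(body)) {
    v <- suppressWarnings(as.numeric(body[[i]][-1L]))
    if (anyNA(v)) abort(sprintf("non-numeric entry at line %d", i + 1L))
    vals[i, ] <- v
  }
  if (any(vals < 0)) {
    bad <- which(rowSums(vals < 0) > 0)[1L]
    abort(sprintf("negative copying length at line %d", bad + 1L))
  }
  out <- tibble::as_tibble(as.data.frame(vals))
  names(out) <- donors
  dplyr::bind_cols(tibble::tibble(recipient = rec), out)
}

#' Write a chunklengths matrix
#'
#' Companion writer to [read_chunklengths()]; emits the same
#' whitespace-delimited dialect so files round-trip.
#'
#' @param x Tibble as returned by [read_chunklengths()]: `recipient` column
#'   plus numeric donor columns.
#' @param path Output path.
#' @return `x`, invisibly.
#' @export
write_chunklengths <- function(x, path) {
  stopifnot(is.data.frame(x), names(x)[1L] == "recipient")
  donors <- names(x)[-1L]
  header <- paste(c("Recipient", donors), collapse = " ")
  rows <- vapply(seq_len(nrow(x)), function(i) {
    paste(c(x$recipient[i],
            formatC(as.numeric(x[i, -1L]), format = "g", digits = 15)),
          collapse = " ")
  }, character(1))
  writeLines(c(header, rows), path)
  invisible(x)
}

#' Normalize copying vectors to copying fractions
#'
#' Divides each recipient's copied lengths by their total `C`, giving the
#' frequency vector `f = l / C` used by the mixture model.
#'
#' @param x Chunklengths tibble (`recipient` + donor columns).
#' @return Tibble of the same shape whose donor columns sum to 1 per row.
#' @export
copying_fractions <- function(x) {
  m <- copy_matrix(x)
  tot <- rowSums(m)
  if (any(tot <= 0)) {
    abort(paste0("degenerate copying vector (total length 0) for recipient: ",
                 paste(x$recipient[tot <= 0], collapse = ", ")))
  }
  m <- m / tot
  dplyr::bind_cols(tibble::tibble(recipient = x$recipient),
                   tibble::as_tibble(as.data.frame(m)))
}

#' Average member copying fractions into surrogate profiles
#'
#' Each surrogate cluster's profile is the unweighted mean of its members'
#' normalized copying vectors (normalizing per individual first makes the
#' average robust to per-individual differences in total copied length).
#'
#' @param x Chunklengths tibble covering the member individuals.
#' @param members Two-column data frame mapping `individual` to `surrogate`
#'   (see [read_cluster_members()]).
#' @return Tibble with columns `surrogate`, `n_ind`, then one column per
#'   donor; each profile row sums to 1.
#' @export
surrogate_profiles <- function(x, members) {
  stopifnot(all(c("individual", "surrogate") %in% names(members)))
  missing <- setdiff(members$individual, x$recipient)
  if (length(missing)) {
    abort(paste0("cluster members absent from chunklengths: ",
                 paste(missing, collapse = ", ")))
  }
  fr <- copying_fractions(x)
  donors <- setdiff(names(fr), "recipient")
  joined <- dplyr::inner_join(members, fr,
                              by = c(individual = "recipient"))
  out <- joined |>
    dplyr::group_by(.data$surrogate) |>
    dplyr::summarise(n_ind = dplyr::n(),
                     dplyr::across(dplyr::all_of(donors), mean),
                     .groups = "drop")
  empty <- setdiff(unique(members$surrogate), out$surrogate)
  if (length(empty)) abort(paste0("empty surrogate cluster: ", paste(empty, collapse = ", ")))
  out
}

#' Collapse cluster-level ancestry proportions into display groups
#'
#' Sums per-surrogate proportions within each group of a cluster-to-group
#' mapping (e.g. collapsing fine reference clusters into named regional
#' groups for presentation). Total ancestry is conserved.
#'
#' @param est Tibble of proportions: `recipient` column plus one numeric
#'   column per surrogate cluster.
#' @param mapping Two-column data frame with `surrogate` and `group`.
#' @return Tibble with `recipient` plus one column per group.
#' @export
collapse_groups <- function(est, mapping) {
  stopifnot(all(c("surrogate", "group") %in% names(mapping)))
  surr <- names(est)[-1L]
  unmapped <- setdiff(surr, mapping$surrogate)
  if (length(unmapped)) {
    abort(paste0("surrogate(s) missing from group mapping: ",
                 paste(unmapped, collapse = ", ")))
  }
  if (anyDuplicated(mapping$surrogate)) {
    abort("each surrogate must map to exactly one group")
  }
  est |>
    tidyr::pivot_longer(-"recipient", names_to = "surrogate",
                        values_to = "proportion") |>
    dplyr::left_join(mapping, by = "surrogate") |>
    dplyr::group_by(.data$recipient, .data$group) |>
    dplyr::summarise(proportion = sum(.data$proportion), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "group", values_from = "proportion") |>
    dplyr::arrange(match(.data$recipient, est$recipient))
}

#' Read a cluster-membership table
#'
#' @param path Two-column TSV (individual, surrogate), no header required;
#'   a header line `individual<TAB>surrogate` is also accepted.
#' @return Tibble with columns `individual`, `surrogate`.
#' @export
read_cluster_members <- function(path) {
  read_two_col(path, c("individual", "surrogate"))
}

#' Read a surrogate-to-group mapping table
#'
#' @param path Two-column TSV (surrogate, group).
#' @return Tibble with columns `surrogate`, `group`.
#' @export
read_group_mapping <- function(path) {
  read_two_col(path, c("surrogate", "group"))
}

read_two_col <- function(path, cols) {
  x <- readr::read_tsv(path, col_names = FALSE, col_types = "cc",
                       progress = FALSE)
  if (identical(tolower(unlist(x[1, ], use.names = FALSE)), cols)) {
    x <- x[-1, ]
  }
  names(x) <- cols
  x
}

# recipient-column tibble -> numeric matrix with recipient rownames
copy_matrix <- function(x) {
  stopifnot(is.data.frame(x), names(x)[1L] %in% c("recipient", "surrogate"))
  m <- as.matrix(x[, !(names(x) %in% c("recipient", "surrogate", "n_ind")),
                   drop = FALSE])
  storage.mode(m) <- "double"
  if (any(m < 0)) abort("negative entry in copying matrix")
  rownames(m) <- x[[1L]]
  m
}

# profiles tibble -> S x D matrix of frequencies, surrogate rownames
profile_matrix <- function(profiles) {
  m <- copy_matrix(profiles)
  bad <- abs(rowSums(m) - 1) > 1e-6
  if (any(bad)) {
    abort(paste0("surrogate profile does not sum to 1: ",
                 paste(rownames(m)[bad], collapse = ", ")))
  }
  m
}
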
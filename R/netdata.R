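#' Multilevel network of collaboration, actions and a causal loop diagram
#'
#' Bundles the three network layers analysed by the multilevel ERGM and the
#' actor attribute table into one validated object:
#' \describe{
#'   \item{A}{binary directed collaboration (nomination) network among
#'     steering-committee members, an \code{n_A x n_A} matrix with zero
#'     diagonal;}
#'   \item{B}{binary directed causal loop diagram (CLD) among system
#'     variables, an \code{n_B x n_B} matrix with zero diagonal. B is
#'     exogenous: it is conditioned on and never modified by the sampler
#'     or the estimator;}
#'   \item{X}{binary actor-by-variable action incidence matrix
#'     (\code{n_A x n_B}). Each actor-variable pair carries a single
#'     non-directed tie variable;}
#'   \item{Y}{per-actor categorical attribute table (organisation type,
#'     education level, gender); may be \code{NULL} when no attribute
#'     effects are used.}
#' }
#'
#' @param A binary matrix \code{n_A x n_A}, zero diagonal.
#' @param B binary matrix \code{n_B x n_B}, zero diagonal.
#' @param X binary matrix \code{n_A x n_B}.
#' @param Y \code{NULL} or a data.frame with one row per actor and a column
#'   \code{actor} of identifiers; remaining columns are categorical
#'   attributes (factors or character). \code{NA} entries are allowed and
#'   never match in homophily statistics.
#' @param actors character vector of unique actor identifiers
#'   (length \code{n_A}, at least 2).
#' @param variables character vector of unique CLD-variable identifiers
#'   (length \code{n_B}, at least 1).
#' @return An object of class \code{"mlnet"}.
#' @examples
#' net <- multilevel_network(
#'   A = matrix(0, 2, 2), B = matrix(0, 1, 1), X = matrix(0, 2, 1),
#'   actors = c("m1", "m2"), variables = "v1"
#' )
#' net
#' @export
multilevel_network <- function(A, B, X, Y = NULL, actors, variables) {
  actors <- as.character(actors)
  variables <- as.character(variables)
  if (anyDuplicated(actors)) stop("actor identifiers must be unique")
  if (anyDuplicated(variables)) stop("variable identifiers must be unique")
  n_A <- length(actors)
  n_B <- length(variables)
  if (n_A < 2) stop("at least 2 actors are required")
  if (n_B < 1) stop("at least 1 CLD variable is required")

  A <- check_binary_matrix(A, n_A, n_A, "A", square = TRUE)
  B <- check_binary_matrix(B, n_B, n_B, "B", square = TRUE)
  X <- check_binary_matrix(X, n_A, n_B, "X", square = FALSE)
  dimnames(A) <- list(actors, actors)
  dimnames(B) <- list(variables, variables)
  dimnames(X) <- list(actors, variables)

  if (!is.null(Y)) {
    Y <- as.data.frame(Y, stringsAsFactors = FALSE)
    if (!"actor" %in% names(Y)) stop("attribute table must have an 'actor' column")
    Y$actor <- as.character(Y$actor)
    if (anyDuplicated(Y$actor)) stop("attribute table has duplicated actors")
    missing_rows <- setdiff(actors, Y$actor)
    if (length(missing_rows)) {
      stop("attribute table lacks rows for actors: ",
           paste(missing_rows, collapse = ", "))
    }
    Y <- Y[match(actors, Y$actor), , drop = FALSE]
    rownames(Y) <- NULL
  }

  structure(
    list(A = A, B = B, X = X, Y = Y, actors = actors, variables = variables),
    class = "mlnet"
  )
}

check_binary_matrix <- function(M, nr, nc, name, square = FALSE) {
  M <- as.matrix(M)
  if (!all(dim(M) == c(nr, nc))) {
    stop(sprintf("%s must be %d x %d, got %d x %d", name, nr, nc,
                 nrow(M), ncol(M)))
  }
  storage.mode(M) <- "integer"
  if (anyNA(M) || !all(M %in% c(0L, 1L))) {
    stop(name, " must be binary (0/1) with no missing entries")
  }
  if (square && any(diag(M) != 0L)) {
    stop(name, " must have a zero diagonal (self-loops are not allowed)")
  }
  M
}

#' @export
print.mlnet <- function(x, ...) {
  cat("Multilevel network\n")
  cat(sprintf("  actors (n_A):        %d\n", length(x$actors)))
  cat(sprintf("  CLD variables (n_B): %d\n", length(x$variables)))
  cat(sprintf("  A arcs: %d   B arcs: %d   X ties: %d\n",
              sum(x$A), sum(x$B), sum(x$X)))
  if (!is.null(x$Y)) {
    cat("  attributes:", paste(setdiff(names(x$Y), "actor"), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Read a multilevel network from layered edge lists
#'
#' Edge lists use one record per line, tab-delimited, with columns
#' \code{layer} (one of \code{A}, \code{B}, \code{X}), \code{from} and
#' \code{to}; a header line is optional. Any further columns (for instance
#' a CLD polarity sign) are read and ignored: layer B is modelled as binary
#' ties. The attribute table is a CSV with a header and an \code{actor}
#' column.
#'
#' Node registries are taken from \code{actors}/\code{variables} when
#' given, otherwise from the attribute table (actors) and, as a last
#' resort, inferred from the edge records. When a registry is explicit,
#' records naming unknown endpoints are collected and reported as an
#' error. Self-loops in A or B are errors naming the offending record;
#' duplicated records are accepted idempotently with a warning.
#'
#' @param edge_paths character vector of edge-list file paths (records from
#'   all files are pooled; layers may be split across files or mixed).
#' @param attr_path optional path to the attribute CSV.
#' @param actors,variables optional explicit registries (character).
#' @return An [multilevel_network()] object.
#' @export
read_multilevel <- function(edge_paths, attr_path = NULL,
                            actors = NULL, variables = NULL) {
  recs <- do.call(rbind, lapply(edge_paths, read_edge_file))
  if (is.null(recs)) {
    recs <- data.frame(layer = character(), from = character(),
                       to = character(), stringsAsFactors = FALSE)
  }
  bad_layer <- setdiff(unique(recs$layer), c("A", "B", "X"))
  if (length(bad_layer)) {
    stop("unknown layer tag(s): ", paste(bad_layer, collapse = ", "))
  }

  Y <- NULL
  if (!is.null(attr_path)) {
    Y <- utils::read.csv(attr_path, stringsAsFactors = FALSE)
    if (!"actor" %in% names(Y)) stop("attribute table must have an 'actor' column")
    Y$actor <- as.character(Y$actor)
  }

  if (is.null(actors)) {
    actors <- if (!is.null(Y)) {
      Y$actor
    } else {
      a <- recs[recs$layer == "A", ]
      x <- recs[recs$layer == "X", ]
      sort(unique(c(a$from, a$to, x$from)))
    }
  }
  if (is.null(variables)) {
    b <- recs[recs$layer == "B", ]
    x <- recs[recs$layer == "X", ]
    variables <- sort(unique(c(b$from, b$to, x$to)))
  }
  actors <- as.character(actors)
  variables <- as.character(variables)

  unknown <- character()
  a <- recs[recs$layer == "A", ]
  b <- recs[recs$layer == "B", ]
  x <- recs[recs$layer == "X", ]
  unknown <- c(
    setdiff(c(a$from, a$to, x$from), actors),
    setdiff(c(b$from, b$to, x$to), variables)
  )
  if (length(unknown)) {
    stop("edge records reference unknown identifiers: ",
         paste(unique(unknown), collapse = ", "))
  }

  selfA <- a[a$from == a$to, ]
  if (nrow(selfA)) {
    stop("self-loop in layer A: (", selfA$from[1], ", ", selfA$to[1], ")")
  }
  selfB <- b[b$from == b$to, ]
  if (nrow(selfB)) {
    stop("self-loop in layer B: (", selfB$from[1], ", ", selfB$to[1], ")")
  }
  if (anyDuplicated(recs[c("layer", "from", "to")])) {
    warning("duplicate edge records found; keeping one copy of each")
  }

  n_A <- length(actors)
  n_B <- length(variables)
  A <- matrix(0L, n_A, n_A)
  B <- matrix(0L, n_B, n_B)
  X <- matrix(0L, n_A, n_B)
  A[cbind(match(a$from, actors), match(a$to, actors))] <- 1L
  B[cbind(match(b$from, variables), match(b$to, variables))] <- 1L
  X[cbind(match(x$from, actors), match(x$to, variables))] <- 1L

  multilevel_network(A, B, X, Y, actors, variables)
}

read_edge_file <- function(path) {
  if (!file.exists(path)) stop("edge-list file not found: ", path)
  first <- readLines(path, n = 1L)
  has_header <- length(first) == 1L &&
    grepl("^layer\t", first, ignore.case = TRUE)
  d <- utils::read.delim(path, header = has_header,
                         stringsAsFactors = FALSE,
                         colClasses = "character")
  if (nrow(d) == 0L) return(NULL)
  if (ncol(d) < 3L) stop("edge-list file needs >= 3 columns: ", path)
  names(d)[1:3] <- c("layer", "from", "to")
  d$layer <- toupper(trimws(d$layer))
  d[c("layer", "from", "to")]
}

#' Write a multilevel network to layered edge lists
#'
#' Writes \code{edges.tsv} (layer/from/to with header), \code{actors.txt},
#' \code{variables.txt}, and \code{attributes.csv} when attributes are
#' present. [read_multilevel()] on the output reproduces the object
#' exactly.
#'
#' @param mnet an \code{mlnet} object.
#' @param dir output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
write_multilevel <- function(mnet, dir) {
  stopifnot(inherits(mnet, "mlnet"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  edges <- rbind(
    edge_records(mnet$A, mnet$actors, mnet$actors, "A"),
    edge_records(mnet$B, mnet$variables, mnet$variables, "B"),
    edge_records(mnet$X, mnet$actors, mnet$variables, "X")
  )
  epath <- file.path(dir, "edges.tsv")
  utils::write.table(edges, epath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  apath <- file.path(dir, "actors.txt")
  vpath <- file.path(dir, "variables.txt")
  writeLines(mnet$actors, apath)
  writeLines(mnet$variables, vpath)
  paths <- c(epath, apath, vpath)
  if (!is.null(mnet$Y)) {
    ypath <- file.path(dir, "attributes.csv")
    utils::write.csv(mnet$Y, ypath, row.names = FALSE)
    paths <- c(paths, ypath)
  }
  invisible(paths)
}

edge_records <- function(M, from_ids, to_ids, tag) {
  idx <- which(M == 1L, arr.ind = TRUE)
  if (nrow(idx) == 0L) {
    return(data.frame(layer = character(), from = character(),
                      to = character(), stringsAsFactors = FALSE))
  }
  data.frame(layer = tag, from = from_ids[idx[, 1]], to = to_ids[idx[, 2]],
             stringsAsFactors = FALSE)
}

#' Restrict a multilevel network to survey respondents
#'
#' The modelled networks contain respondents only: nominations sent to or
#' received from non-respondents are dropped, X is restricted to
#' respondent rows, and B is unchanged (the CLD does not depend on who
#' answered the survey).
#'
#' @param mnet an \code{mlnet} object.
#' @param respondents character vector of respondent actor ids (non-empty,
#'   a subset of the actor registry).
#' @return A new \code{mlnet} over the respondent registry.
#' @export
restrict_to_respondents <- function(mnet, respondents) {
  stopifnot(inherits(mnet, "mlnet"))
  respondents <- as.character(respondents)
  if (length(respondents) == 0L) stop("respondent set must be non-empty")
  unknown <- setdiff(respondents, mnet$actors)
  if (length(unknown)) {
    stop("unknown respondent id(s): ", paste(unknown, collapse = ", "))
  }
  keep <- mnet$actors %in% respondents
  Y <- if (is.null(mnet$Y)) NULL else mnet$Y[keep, , drop = FALSE]
  multilevel_network(
    A = mnet$A[keep, keep, drop = FALSE],
    B = mnet$B,
    X = mnet$X[keep, , drop = FALSE],
    Y = Y,
    actors = mnet$actors[keep],
    variables = mnet$variables
  )
}

round_half_up <- function(x) floor(x + 0.5)

#' Descriptive summary of a multilevel network
#'
#' Mirrors the descriptive table reported for each community: response
#' rate, collaboration out-degree mean and range, actions per member mean
#' and range, CLD size, and per-category attribute counts with percentages
#' rounded half-up to integers.
#'
#' @param mnet an \code{mlnet} object (respondents only).
#' @param invited number of invited committee members (>= number of
#'   actors, > 0).
#' @return A list of class \code{"mlnet_summary"}.
#' @export
descriptive_summary <- function(mnet, invited) {
  stopifnot(inherits(mnet, "mlnet"))
  if (length(invited) != 1L || is.na(invited) || invited <= 0) {
    stop("invited must be a positive count")
  }
  n_A <- length(mnet$actors)
  if (invited < n_A) stop("invited must be >= number of respondents")
  outdeg <- rowSums(mnet$A)
  actions <- rowSums(mnet$X)
  attributes <- NULL
  if (!is.null(mnet$Y)) {
    attributes <- lapply(setdiff(names(mnet$Y), "actor"), function(col) {
      v <- mnet$Y[[col]]
      tab <- table(factor(v), useNA = "no")
      data.frame(
        category = names(tab),
        n = as.integer(tab),
        percent = round_half_up(100 * as.integer(tab) / n_A),
        stringsAsFactors = FALSE
      )
    })
    names(attributes) <- setdiff(names(mnet$Y), "actor")
  }
  structure(list(
    n_respondents = n_A,
    invited = as.integer(invited),
    response_rate_percent = round_half_up(100 * n_A / invited),
    outdegree = list(mean = mean(outdeg), min = min(outdeg), max = max(outdeg)),
    actions = list(mean = mean(actions), min = min(actions), max = max(actions)),
    n_cld_variables = length(mnet$variables),
    attributes = attributes
  ), class = "mlnet_summary")
}

#' @export
print.mlnet_summary <- function(x, ...) {
  cat(sprintf("Respondents: %d of %d invited (%d%%)\n",
              x$n_respondents, x$invited, x$response_rate_percent))
  cat(sprintf("Collaboration out-degree: mean %.1f (min %d, max %d)\n",
              x$outdegree$mean, x$outdegree$min, x$outdegree$max))
  cat(sprintf("Actions per member: mean %.1f (min %d, max %d)\n",
              x$actions$mean, x$actions$min, x$actions$max))
  cat(sprintf("CLD variables: %d\n", x$n_cld_variables))
  for (nm in names(x$attributes)) {
    cat(nm, ":\n", sep = "")
    a <- x$attributes[[nm]]
    for (k in seq_len(nrow(a))) {
      cat(sprintf("  %-38s %d (%d%%)\n", a$category[k], a$n[k], a$percent[k]))
    }
  }
  invisible(x)
}

#' Export a summary as JSON
#'
#' @param summary an \code{mlnet_summary} from [descriptive_summary()].
#' @param path output file path.
#' @return Invisibly, \code{path}.
#' @export
write_summary_json <- function(summary, path) {
  jsonlite::write_json(unclass(summary), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}
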
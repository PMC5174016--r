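#' Generate a four-level subsystem-style function catalog
#'
#' Builds a random rooted hierarchy with four levels (subsystem hierarchy 1,
#' 2, 3 and the function level), mimicking the structure of SEED-style
#' subsystem annotations. Every function (leaf) has exactly one ancestor at
#' each higher level; node names are unique within a level. When a level has
#' at least as many nodes as its parent level, every parent receives at least
#' one child, so no category is structurally empty.
#'
#' @param level_sizes integer vector of length 4: number of categories at
#'   hierarchy levels 1, 2, 3 and at the function level. All must be >= 1;
#'   sizes need not be non-decreasing.
#' @param seed integer seed; identical seeds give byte-identical catalogs.
#' @return An object of class `function_hierarchy`: a list with `levels`
#'   (named character vectors of node names per level), `parent` (child ->
#'   parent maps for levels 2..4) and `paths` (a data frame with one row per
#'   function and columns `h1`, `h2`, `h3`, `fun`).
#' @examples
#' cat4 <- generate_function_catalog(c(2, 4, 8, 16), seed = 1)
#' nrow(cat4$paths)  # 16 functions, each with a unique 4-level path
#' @export
generate_function_catalog <- function(level_sizes, seed = 1L) {
  if (length(level_sizes) != 4L) {
    stop("`level_sizes` must have length 4", call. = FALSE)
  }
  sizes <- vapply(seq_along(level_sizes), function(i) {
    assert_positive_int(level_sizes[i], sprintf("level_sizes[%d]", i))
  }, integer(1))

  prefixes <- c("H1", "H2", "H3", "F")
  widths <- c(2L, 3L, 3L, 4L)
  nodes <- lapply(1:4, function(k) {
    sprintf("%s_%0*d", prefixes[k], widths[k], seq_len(sizes[k]))
  })

  parent <- withr::with_seed(seed, {
    lapply(2:4, function(k) {
      np <- sizes[k - 1L]
      nc <- sizes[k]
      # Cover every parent first (when possible), then assign the rest at random.
      p <- if (nc >= np) {
        c(nodes[[k - 1L]], sample(nodes[[k - 1L]], nc - np, replace = TRUE))
      } else {
        sample(nodes[[k - 1L]], nc, replace = FALSE)
      }
      stats::setNames(sample(p), nodes[[k]])
    })
  })
  names(parent) <- c("h2", "h3", "fun")

  h3 <- parent$fun[nodes[[4]]]
  h2 <- parent$h3[h3]
  h1 <- parent$h2[h2]
  paths <- data.frame(
    h1 = unname(h1), h2 = unname(h2), h3 = unname(h3), fun = nodes[[4]],
    stringsAsFactors = FALSE
  )

  structure(
    list(
      levels = stats::setNames(nodes, c("h1", "h2", "h3", "fun")),
      parent = parent,
      paths = paths
    ),
    class = "function_hierarchy"
  )
}

#' @export
print.function_hierarchy <- function(x, ...) {
  cat("function_hierarchy:",
      paste(vapply(x$levels, length, integer(1)), collapse = " / "),
      "categories at levels 1-4\n")
  invisible(x)
}

#' Map functions to their ancestor category at a hierarchy level
#'
#' @param hierarchy a `function_hierarchy`.
#' @param functions character vector of function (leaf) names.
#' @param level target level, 1..4 (level 4 returns the input).
#' @return character vector of ancestor names, `NA` for unknown functions.
#' @export
ancestor_at_level <- function(hierarchy, functions, level) {
  stopifnot(inherits(hierarchy, "function_hierarchy"))
  col <- level_column(level)
  idx <- match(functions, hierarchy$paths$fun)
  hierarchy$paths[[col]][idx]
}

# Leaf functions under a named category at any level; errors if unknown.
functions_under <- function(hierarchy, category) {
  stopifnot(inherits(hierarchy, "function_hierarchy"))
  p <- hierarchy$paths
  for (col in c("h1", "h2", "h3", "fun")) {
    if (category %in% p[[col]]) return(p$fun[p[[col]] == category])
  }
  stop(sprintf("unknown pathway/category: '%s'", category), call. = FALSE)
}
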
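#' Obstacle catalogs
#'
#' An obstacle catalog lists every obstacle that can appear in a lane,
#' together with its semantic category. Categories follow the five-level
#' scheme used throughout the package: `empty` (the control lane with
#' nothing in it), `object` (inanimate objects), `animal`, `human`
#' (single humans), and `group` (composite obstacles, e.g. a human
#' together with an animal). Exactly one entry must be the empty lane.
#'
#' @param obstacle_id character vector of unique, whitespace-free tokens.
#' @param category character vector of category labels, one per obstacle;
#'   each must be one of `empty`, `object`, `animal`, `human`, `group`.
#' @param display_name optional human-readable names (defaults to the ids).
#'
#' @return A data frame of class `obstacle_catalog` with columns
#'   `obstacle_id`, `category`, `display_name`, in the given (canonical)
#'   order.
#' @export
#' @examples
#' cat18 <- default_catalog()
#' nrow(cat18)                      # 18
#' table(cat18$category)
obstacle_catalog <- function(obstacle_id, category, display_name = obstacle_id) {
  obstacle_id <- as.character(obstacle_id)
  category <- as.character(category)
  display_name <- as.character(display_name)
  if (length(obstacle_id) != length(category) ||
      length(obstacle_id) != length(display_name)) {
    stop("obstacle_id, category and display_name must have equal length")
  }
  if (any(!nzchar(obstacle_id)) || any(grepl("\\s", obstacle_id))) {
    stop("obstacle_id tokens must be non-empty and contain no whitespace")
  }
  if (anyDuplicated(obstacle_id)) {
    stop("duplicate obstacle_id: ",
         paste(unique(obstacle_id[duplicated(obstacle_id)]), collapse = ", "))
  }
  bad <- setdiff(unique(category), obstacle_categories())
  if (length(bad)) {
    stop("unknown category: ", paste(bad, collapse = ", "))
  }
  if (sum(category == "empty") != 1L) {
    stop("catalog must contain exactly one obstacle with category 'empty'")
  }
  out <- data.frame(
    obstacle_id = obstacle_id,
    category = category,
    display_name = display_name,
    stringsAsFactors = FALSE
  )
  class(out) <- c("obstacle_catalog", "data.frame")
  out
}

#' @rdname obstacle_catalog
#' @export
obstacle_categories <- function() {
  c("empty", "object", "animal", "human", "group")
}

#' Default 18-obstacle catalog
#'
#' The default catalog mirrors the structure of the study design the
#' package simulates: one empty control lane, 3 inanimate objects, 6
#' animals, 6 single humans and 2 composite groups (18 obstacles, 153
#' unordered pairings). Obstacles named in running text (boy, man, woman,
#' dog, goat, boar, deer) keep those names; the remaining identifiers are
#' schematic placeholders with the right category structure.
#'
#' @return An [obstacle_catalog()].
#' @export
default_catalog <- function() {
  obstacle_catalog(
    obstacle_id = c(
      "empty",
      "pylon", "trash_bin", "hay_bale",
      "boar", "goat", "deer", "sheep", "pig", "dog",
      "elderly_man", "elderly_woman", "woman", "man", "girl", "boy",
      "human_animal_group", "human_group"
    ),
    category = c(
      "empty",
      rep("object", 3L),
      rep("animal", 6L),
      rep("human", 6L),
      rep("group", 2L)
    ),
    display_name = c(
      "empty lane",
      "traffic pylon", "trash bin", "hay bale",
      "wild boar", "goat", "deer", "sheep", "pig", "dog",
      "elderly man", "elderly woman", "adult woman", "adult man",
      "girl", "boy",
      "group of humans and animals", "group of humans"
    )
  )
}

#' @export
print.obstacle_catalog <- function(x, ...) {
  cat("Obstacle catalog:", nrow(x), "obstacles,",
      length(unique(x$category)), "categories\n")
  print.data.frame(x, row.names = FALSE, ...)
  invisible(x)
}

# id of the unique empty-lane obstacle
empty_obstacle_id <- function(catalog) {
  catalog$obstacle_id[catalog$category == "empty"]
}

assert_catalog <- function(catalog) {
  if (!inherits(catalog, "obstacle_catalog")) {
    stop("expected an obstacle_catalog; see default_catalog()")
  }
  invisible(catalog)
}
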
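#' Grouped, stratified train/test split
#'
#' Splitting is GROUPED by `source_id` — all augmented variants of one
#' photograph land in the same partition, so no content leaks from train
#' into test — and STRATIFIED by grade, so the 4:1 ratio holds within
#' every class. Deterministic given `seed`.
#'
#' @param manifest Data frame where every row is one dataset item, with
#'   at least `source_id` and `grade` columns.
#' @param train_fraction Fraction of source groups per grade assigned to
#'   training (default 4/5).
#' @param seed Integer seed for the per-grade sampling.
#' @param require_test If `TRUE` (default), every grade must end up with
#'   at least one test group, so grades with fewer than 2 source groups
#'   are an error. Set `FALSE` to allow `train_fraction = 1`.
#' @return `manifest` with a `partition` column (`"train"`/`"test"`).
#' @export
split_dataset <- function(manifest, train_fraction = 0.8, seed = 1L,
                          require_test = TRUE) {
  stopifnot(all(c("source_id", "grade") %in% names(manifest)),
            train_fraction >= 0, train_fraction <= 1)
  groups <- unique(manifest[, c("source_id", "grade")])
  if (anyDuplicated(groups$source_id))
    stop("a source_id maps to more than one grade", call. = FALSE)
  train_ids <- withr::with_seed(as.integer(seed), {
    unlist(lapply(split(groups$source_id, groups$grade), function(ids) {
      if (require_test && length(ids) < 2L)
        stop("grade with fewer than 2 source groups cannot be split",
             call. = FALSE)
      n_train <- round(train_fraction * length(ids))
      if (require_test) n_train <- min(n_train, length(ids) - 1L)
      sample(ids, n_train)
    }), use.names = FALSE)
  })
  manifest$partition <- ifelse(manifest$source_id %in% train_ids,
                               "train", "test")
  manifest
}

#' Prepare a detector-ready dataset
#'
#' Runs the full construction: read each annotated source image, produce
#' the five right-angle augmentation variants, whiten the background of
#' every variant by edge-seeded flood fill, convert annotations to YOLO
#' labels, and split grouped-by-source and stratified-by-grade into
#' train/test. The output layout (`images/{train,test}`,
#' `labels/{train,test}`, `dataset.yaml`) is directly consumable by a
#' YOLO-style detector. Augmentation is applied before extraction,
#' matching the construction order of the original corpus; because the
#' transforms are pixel permutations the two orders give identical
#' pixels, and `order = "extract_first"` is available.
#'
#' @param input_dir Directory of source images with same-stem VOC `.xml`
#'   annotations (as written by [generate_dataset()] or labelimg).
#' @param out_dir Output directory.
#' @param max_distance Flood-fill color-distance threshold.
#' @param connectivity,metric Passed to [flood_params()].
#' @param train_fraction Train share of source groups per grade.
#' @param seed Integer seed (split determinism; recorded in the
#'   manifest).
#' @param augment Produce the five variants per source (`TRUE`) or only
#'   the identity (`FALSE`).
#' @param extract Whiten backgrounds (`TRUE`) or copy pixels unchanged.
#' @param order `"augment_first"` (default) or `"extract_first"`.
#' @param grades A [grade_map()].
#' @param missing_annotation `"skip"` (default; warn and list) or
#'   `"error"`.
#' @return Invisibly, the manifest data frame (also written as
#'   `manifest.csv`): `source_id`, `variant`, `grade`, `image_path`,
#'   `label_path`, `partition`.
#' @export
prepare_dataset <- function(input_dir, out_dir, max_distance,
                            connectivity = 4L, metric = "euclidean",
                            train_fraction = 0.8, seed = 1L,
                            augment = TRUE, extract = TRUE,
                            order = c("augment_first", "extract_first"),
                            grades = grade_map(),
                            missing_annotation = c("skip", "error")) {
  order <- match.arg(order)
  missing_annotation <- match.arg(missing_annotation)
  params <- flood_params(max_distance, connectivity, metric)

  imgs <- list.files(input_dir, pattern = "\\.(png|jpe?g)$",
                     ignore.case = TRUE)
  anns <- file.path(input_dir,
                    paste0(tools::file_path_sans_ext(imgs), ".xml"))
  missing <- !file.exists(anns)
  if (any(missing)) {
    msg <- paste("images without annotation:",
                 paste(imgs[missing], collapse = ", "))
    if (missing_annotation == "error") stop(msg, call. = FALSE)
    warning(msg, ", skipped", call. = FALSE)
    imgs <- imgs[!missing]; anns <- anns[!missing]
  }
  if (length(imgs) == 0L) stop("no annotated images found", call. = FALSE)

  for (d in c("images/train", "images/test", "labels/train", "labels/test"))
    dir.create(file.path(out_dir, d), recursive = TRUE, showWarnings = FALSE)

  # one manifest row per output item; grade of a source = grade of its
  # first annotated object
  sources <- lapply(seq_along(imgs), function(i) {
    ann <- parse_voc(anns[i])
    if (nrow(ann$boxes) == 0L)
      stop("annotation with no objects: ", anns[i], call. = FALSE)
    list(id = tools::file_path_sans_ext(imgs[i]),
         img_file = file.path(input_dir, imgs[i]), ann = ann)
  })
  variants <- if (augment) transform_kinds else "identity"
  manifest <- do.call(rbind, lapply(sources, function(s) {
    data.frame(source_id = s$id, variant = unname(transform_tags[variants]),
               grade = s$ann$boxes$grade[1L], stringsAsFactors = FALSE)
  }))
  manifest <- split_dataset(manifest, train_fraction, seed,
                            require_test = train_fraction < 1)

  counts <- c(sources = length(sources), images = 0L, train = 0L, test = 0L)
  rows <- vector("list", nrow(manifest))
  k <- 0L
  for (s in sources) {
    img <- read_image(s$img_file)
    if (extract && order == "extract_first")
      img <- extract_foreground(img, params)
    w <- img_width(img); h <- img_height(img)
    part <- manifest$partition[manifest$source_id == s$id][1L]
    for (t in variants) {
      timg <- apply_to_image(t, img)
      tbox <- apply_to_box(t, s$ann$boxes, w, h)
      if (extract && order == "augment_first")
        timg <- extract_foreground(timg, params)
      dims <- transformed_dims(t, w, h)
      stem <- paste0(s$id, "_", transform_tags[t])
      img_rel <- file.path("images", part, paste0(stem, ".png"))
      lab_rel <- file.path("labels", part, paste0(stem, ".txt"))
      write_image(timg, file.path(out_dir, img_rel))
      write_yolo_file(to_yolo(tbox, dims["width"], dims["height"], grades),
                      file.path(out_dir, lab_rel))
      k <- k + 1L
      rows[[k]] <- data.frame(
        source_id = s$id, variant = unname(transform_tags[t]),
        grade = s$ann$boxes$grade[1L], image_path = img_rel,
        label_path = lab_rel, partition = part, stringsAsFactors = FALSE)
      counts["images"] <- counts["images"] + 1L
      counts[part] <- counts[part] + 1L
    }
  }
  out <- do.call(rbind, rows)
  out <- out[base::order(out$source_id, out$variant), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "seed") <- as.integer(seed)
  utils::write.csv(cbind(out, seed = as.integer(seed)),
                   file.path(out_dir, "manifest.csv"), row.names = FALSE)
  write_dataset_yaml(file.path(out_dir, "dataset.yaml"),
                     "images/train", "images/test", grades)
  message(sprintf("prepared %d images from %d sources (%d train / %d test)",
                  counts["images"], counts["sources"], counts["train"],
                  counts["test"]))
  invisible(out)
}

#' Run prepare_dataset from a YAML config
#'
#' The config file mirrors the arguments of [prepare_dataset()]
#' (`input_dir`, `out_dir`, `max_distance`, and optionally
#' `connectivity`, `metric`, `train_fraction`, `seed`, `augment`,
#' `extract`, `order`, `grade_names`).
#'
#' @param config_path Path to the YAML file.
#' @return The manifest, invisibly.
#' @export
prepare_dataset_config <- function(config_path) {
  cfg <- yaml::read_yaml(config_path)
  for (key in c("input_dir", "out_dir", "max_distance"))
    if (is.null(cfg[[key]]))
      stop("config is missing required key: ", key, call. = FALSE)
  prepare_dataset(
    input_dir = cfg$input_dir, out_dir = cfg$out_dir,
    max_distance = cfg$max_distance,
    connectivity = cfg$connectivity %||% 4L,
    metric = cfg$metric %||% "euclidean",
    train_fraction = cfg$train_fraction %||% 0.8,
    seed = cfg$seed %||% 1L,
    augment = cfg$augment %||% TRUE,
    extract = cfg$extract %||% TRUE,
    order = cfg$order %||% "augment_first",
    grades = grade_map(cfg$grade_names %||% paste0("grade_", 1:4))
  )
}
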
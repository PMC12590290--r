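#' Particle annotation set
#'
#' Ground-truth (or predicted) boxes for a collection of micrographs, with a
#' single foreground category "particle" (COCO category id 1; background is
#' implicit). Boxes are stored in normalized center form against each
#' image's recorded size.
#'
#' @param annotations data.frame with columns `micrograph_id`, `cx`, `cy`,
#'   `w`, `h` (normalized center form) and optionally `category_id`.
#' @param images data.frame with columns `id`, `micrograph_id`, `width`,
#'   `height`.
#' @return A list of class `annotation_set`.
#' @export
annotation_set <- function(annotations, images) {
  if (nrow(annotations) > 0) {
    if (is.null(annotations$category_id)) annotations$category_id <- 1L
    bad <- !annotations$micrograph_id %in% images$micrograph_id
    if (any(bad))
      stop("annotations reference unknown micrographs: ",
           paste(unique(annotations$micrograph_id[bad]), collapse = ", "))
    validate_norm_box(as.matrix(annotations[, c("cx", "cy", "w", "h")]))
  }
  structure(list(annotations = annotations, images = images,
                 categories = data.frame(id = 1L, name = "particle")),
            class = "annotation_set")
}

boxes_for <- function(annos, micrograph_id) {
  a <- annos$annotations
  as.matrix(a[a$micrograph_id == micrograph_id, c("cx", "cy", "w", "h"),
              drop = FALSE])
}

#' Read COCO-style detection annotations
#'
#' Expects the COCO layout (`images`, `annotations`, `categories` arrays;
#' boxes as `[x_min, y_min, w, h]` in pixels). Boxes are converted to
#' normalized center form against each image's recorded size; boxes
#' overhanging the frame by more than one pixel are clamped with a warning.
#' A single foreground category is enforced.
#'
#' @param json_path Path to the COCO JSON file.
#' @return An [annotation_set()].
#' @export
read_coco <- function(json_path) {
  j <- jsonlite::fromJSON(json_path, simplifyVector = TRUE)
  imgs <- as.data.frame(j$images)
  if (nrow(imgs) == 0) stop("COCO file lists no images")
  if (!is.null(j$categories) && NROW(j$categories) > 1)
    stop("expected a single 'particle' category, found ", NROW(j$categories))
  images <- data.frame(id = imgs$id,
                       micrograph_id = imgs$file_name,
                       width = imgs$width, height = imgs$height,
                       stringsAsFactors = FALSE)
  ann <- j$annotations
  if (is.null(ann) || NROW(ann) == 0) {
    annotations <- data.frame(micrograph_id = character(0),
                              cx = numeric(0), cy = numeric(0),
                              w = numeric(0), h = numeric(0),
                              category_id = integer(0))
    return(annotation_set(annotations, images))
  }
  ann <- as.data.frame(ann)
  miss <- !ann$image_id %in% images$id
  if (any(miss))
    stop("annotation references unknown image id: ",
         paste(unique(ann$image_id[miss]), collapse = ", "))
  bb <- do.call(rbind, ann$bbox)
  row <- match(ann$image_id, images$id)
  W <- images$width[row]; H <- images$height[row]
  x1 <- bb[, 1]; y1 <- bb[, 2]; x2 <- bb[, 1] + bb[, 3]; y2 <- bb[, 2] + bb[, 4]
  over <- x1 < -1 | y1 < -1 | x2 > W + 1 | y2 > H + 1
  if (any(over))
    warning(sum(over), " box(es) exceed image bounds by >1 px; clamped")
  x1 <- pmin(pmax(x1, 0), W); x2 <- pmin(pmax(x2, 0), W)
  y1 <- pmin(pmax(y1, 0), H); y2 <- pmin(pmax(y2, 0), H)
  annotations <- data.frame(
    micrograph_id = images$micrograph_id[row],
    cx = (x1 + x2) / 2 / W, cy = (y1 + y2) / 2 / H,
    w = (x2 - x1) / W, h = (y2 - y1) / H,
    category_id = if (!is.null(ann$category_id)) ann$category_id else 1L,
    stringsAsFactors = FALSE)
  annotation_set(annotations, images)
}

#' Write an annotation set as COCO JSON
#'
#' Inverse of [read_coco()]: normalized center-form boxes are converted back
#' to pixel `[x_min, y_min, w, h]` against each image's recorded size. Key
#' ordering and numeric formatting are deterministic, so identical inputs
#' produce byte-identical files.
#'
#' @param annos An [annotation_set()].
#' @param out_path Output JSON path.
#' @export
write_coco <- function(annos, out_path) {
  imgs <- annos$images
  images <- lapply(seq_len(nrow(imgs)), function(i)
    list(id = imgs$id[i], file_name = imgs$micrograph_id[i],
         width = imgs$width[i], height = imgs$height[i]))
  a <- annos$annotations
  anns <- lapply(seq_len(nrow(a)), function(i) {
    row <- match(a$micrograph_id[i], imgs$micrograph_id)
    W <- imgs$width[row]; H <- imgs$height[row]
    list(id = i, image_id = imgs$id[row],
         category_id = a$category_id[i],
         bbox = c((a$cx[i] - a$w[i] / 2) * W, (a$cy[i] - a$h[i] / 2) * H,
                  a$w[i] * W, a$h[i] * H),
         area = a$w[i] * W * a$h[i] * H, iscrowd = 0L)
  })
  out <- list(images = images, annotations = anns,
              categories = list(list(id = 1L, name = "particle")))
  json <- jsonlite::toJSON(out, auto_unbox = TRUE, digits = I(10),
                           pretty = TRUE)
  writeLines(json, out_path, useBytes = TRUE)
  invisible(out_path)
}
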
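test_that("skelcsv write/read round-trips sequences exactly", {
  set.seed(11)
  for (scheme in c("J7", "J15", "J20")) {
    s <- random_sequence(n = 4, joints = joint_scheme(scheme)$members)
    p <- withr::local_tempfile(fileext = ".skelcsv")
    write_sequence(s, p)
    s2 <- read_sequence(p, sequence_id = s$sequence_id)
    expect_identical(s2$joints, s$joints)
    expect_identical(s2$coords, s$coords)
    # a second write is byte-identical
    p2 <- withr::local_tempfile(fileext = ".skelcsv")
    write_sequence(s2, p2)
    expect_identical(readLines(p), readLines(p2))
  }
  # header declares all joints
  s20 <- random_sequence(n = 2, joints = canonical_joints())
  p <- withr::local_tempfile(fileext = ".skelcsv")
  write_sequence(s20, p)
  expect_match(readLines(p)[1], "^#joints=head,neck,torso,")
  expect_length(strsplit(sub("^#joints=", "", readLines(p)[1]), ",")[[1]], 20)
})

test_that("malformed sequence files are rejected with line numbers", {
  p <- withr::local_tempfile(fileext = ".skelcsv")
  writeLines(character(0), p)
  expect_error(read_sequence(p), "empty file")

  writeLines(c("#joints=torso,neck", "0,0,0,0,1,0", "0,0,0,0,1"), p)
  expect_error(read_sequence(p), "line 3")

  writeLines(c("#joints=torso,neck", "0,0,0,0,NaN,0"), p)
  expect_error(read_sequence(p), "non-finite")

  writeLines(c("#joints=torso,neck", "0,0,0,0,x,0"), p)
  expect_error(read_sequence(p), "line 2")

  expect_error(read_sequence(tempfile()), "no such file")
  expect_error(read_sequence(p, dialect = "nope"), "dialect")
})

test_that("sequence construction enforces the frame invariants", {
  coords <- array(0, dim = c(2, 2, 3))
  coords[, 2, 2] <- 1
  expect_s3_class(skeleton_sequence(coords, c("torso", "neck")),
                  "skeleton_sequence")
  expect_error(skeleton_sequence(coords, c("torso", "head")), "neck")
  expect_error(skeleton_sequence(coords, c("torso", "bogus")), "unknown joint")
  bad <- coords; bad[1, 1, 1] <- NA
  expect_error(skeleton_sequence(bad, c("torso", "neck")), "non-finite")
  expect_error(skeleton_sequence(coords[0, , , drop = FALSE],
                                 c("torso", "neck")), "at least one frame")
})

test_that("joint subset selection keeps canonical order and errors on absent joints", {
  set.seed(4)
  s20 <- random_sequence(n = 3, joints = canonical_joints())
  s7 <- select_joints(s20, "J7")
  expect_identical(s7$joints, joint_scheme("J7")$members)
  expect_equal(n_frames(s7), 3)
  expect_identical(s7$coords[, "torso", ], s20$coords[, "torso", ])

  s15 <- random_sequence(n = 3, joints = joint_scheme("J15")$members)
  expect_error(select_joints(s15, "J20"), "unsupported scheme")
  # identity on the joint set
  expect_identical(select_joints(s15, "J15")$coords, s15$coords)
})

test_that("manifest round-trips and resolves relative paths", {
  td <- withr::local_tempdir()
  man <- data.frame(sequence_id = c("s1", "s2"), actor_id = c("a", "b"),
                    label = c("x", "y"),
                    path = c("s1.skelcsv", "s2.skelcsv"))
  write_manifest(man, file.path(td, "manifest.csv"))
  back <- read_manifest(file.path(td, "manifest.csv"))
  expect_identical(back$sequence_id, man$sequence_id)
  expect_identical(basename(back$path), man$path)
  expect_identical(dirname(back$path), rep(td, 2))
})

test_that("mirroring is an involution, an isometry, and swaps left/right", {
  set.seed(21)
  for (rep_i in 1:5) {
    s <- random_sequence(n = 3, joints = joint_scheme("J15")$members)
    m <- mirror_sequence(s)
    mm <- mirror_sequence(m)
    expect_lt(max(abs(mm$coords - s$coords)), 1e-9)
    # isometry: all pairwise inter-joint distances preserved per frame
    # (compared after undoing the left/right label swap, which permutes
    # the joint slots without changing the distance multiset)
    for (f in seq_len(n_frames(s))) {
      d0 <- dist(get_frame(s, f))
      d1 <- dist(swap_lr_frame(get_frame(m, f)))
      expect_lt(max(abs(d0 - d1)), 1e-9)
    }
  }
  # torso lies on the plane: fixed point of the reflection
  s <- random_sequence(n = 2)
  m <- mirror_sequence(s)
  expect_lt(max(abs(m$coords[, "torso", ] - s$coords[, "torso", ])), 1e-12)
  # signed-distance geometry: left hand at +d maps to right hand at -d
  fr <- get_frame(s, 1)
  n <- fr["right_shoulder", ] - fr["left_shoulder", ]
  n <- n / sqrt(sum(n^2))
  d_left <- sum((fr["left_hand", ] - fr["torso", ]) * n)
  fr_m <- get_frame(m, 1)
  d_right_m <- sum((fr_m["right_hand", ] - fr_m["torso", ]) * n)
  expect_equal(d_right_m, -d_left, tolerance = 1e-9)
  # plane-parallel component of that joint is preserved
  par0 <- (fr["left_hand", ] - fr["torso", ]) - d_left * n
  par1 <- (fr_m["right_hand", ] - fr_m["torso", ]) - d_right_m * n
  expect_equal(par1, par0, tolerance = 1e-9)
})

test_that("mirroring requires shoulders and commutes with symmetric joint selection", {
  s7 <- random_sequence(n = 2, joints = joint_scheme("J7")$members)
  expect_error(mirror_sequence(s7), "shoulder")
  set.seed(33)
  s <- random_sequence(n = 3, joints = canonical_joints())
  a <- select_joints(mirror_sequence(s), "J15")
  b <- mirror_sequence(select_joints(s, "J15"))
  expect_lt(max(abs(a$coords - b$coords)), 1e-12)
})
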
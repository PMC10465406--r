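Package: cardiocfd
Title: Geometry-Prescribed CFD of Intra-Ventricular Flow with Ultrasound Comparison
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale pipeline for geometry-prescribed computational fluid
    dynamics of a compressing ventricle-like cavity. Cyclic wall motion is
    recovered from a 4D image sequence by diffeomorphic demons registration,
    assembled into a cyclic displacement field, smoothed temporally with
    periodic splines and prescribed to a moving simplex mesh. The
    incompressible Navier-Stokes equations are solved on the moving mesh in
    arbitrary Lagrangian-Eulerian form with Taylor-Hood mixed finite elements,
    with stationary ramp initialisation, multi-cycle execution, cycle
    convergence and mesh-independence reporting. Simulated flow is compared to
    planar two-dimensional vector-flow records via phase alignment, rigid
    landmark co-registration, plane slicing onto a common grid, region-of-
    interest time binning and linear regression. A synthetic dynamic-phantom
    generator supplies image sequences, ground-truth motion and emulated
    vector-flow measurements with known truth, so that every stage is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    Matrix,
    jsonlite,
    yaml,
    RNifti
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
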
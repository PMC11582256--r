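/* Minimal FastMRI-dialect HDF5 I/O.
 *
 * Layout: dataset "kspace", 4-D (slices x coils x ky x kx), compound {r,i}
 * doubles (the convention h5py uses for complex arrays); optional dataset
 * "reconstruction_rss", 3-D real (slices x ky x kx); root attributes
 * "scanner", "split" (strings) and "scale_factor" (double).
 *
 * R complex numbers are {double r, i} structs, memory-compatible with the
 * compound type, so buffers are passed through without repacking. The R side
 * hands arrays whose first R dimension is kx (fastest-varying), matching the
 * C-order HDF5 layout.
 */

#include <R.h>
#include <Rinternals.h>
#include <hdf5.h>
#include <string.h>

static hid_t complex_memtype(void)
{
    hid_t t = H5Tcreate(H5T_COMPOUND, 2 * sizeof(double));
    H5Tinsert(t, "r", 0, H5T_NATIVE_DOUBLE);
    H5Tinsert(t, "i", sizeof(double), H5T_NATIVE_DOUBLE);
    return t;
}

static void write_string_attr(hid_t loc, const char *name, const char *value)
{
    hid_t space = H5Screate(H5S_SCALAR);
    hid_t type = H5Tcopy(H5T_C_S1);
    H5Tset_size(type, H5T_VARIABLE);
    H5Tset_cset(type, H5T_CSET_UTF8);
    hid_t attr = H5Acreate2(loc, name, type, space, H5P_DEFAULT, H5P_DEFAULT);
    H5Awrite(attr, type, &value);
    H5Aclose(attr); H5Tclose(type); H5Sclose(space);
}

static void write_double_attr(hid_t loc, const char *name, double value)
{
    hid_t space = H5Screate(H5S_SCALAR);
    hid_t attr = H5Acreate2(loc, name, H5T_NATIVE_DOUBLE, space,
                            H5P_DEFAULT, H5P_DEFAULT);
    H5Awrite(attr, H5T_NATIVE_DOUBLE, &value);
    H5Aclose(attr); H5Sclose(space);
}

/* returns allocated CHARSXP-ready string or NULL if attribute absent */
static SEXP read_string_attr(hid_t loc, const char *name)
{
    if (H5Aexists(loc, name) <= 0) return R_NilValue;
    hid_t attr = H5Aopen(loc, name, H5P_DEFAULT);
    hid_t type = H5Aget_type(attr);
    SEXP out = R_NilValue;
    if (H5Tis_variable_str(type) > 0) {
        char *buf = NULL;
        hid_t mt = H5Tget_native_type(type, H5T_DIR_ASCEND);
        H5Aread(attr, mt, &buf);
        if (buf) { out = Rf_mkString(buf); free(buf); }
        H5Tclose(mt);
    } else {
        size_t n = H5Tget_size(type);
        char *buf = (char *) R_alloc(n + 1, 1);
        memset(buf, 0, n + 1);
        hid_t mt = H5Tcopy(type);
        H5Aread(attr, mt, buf);
        out = Rf_mkString(buf);
        H5Tclose(mt);
    }
    H5Tclose(type); H5Aclose(attr);
    return out;
}

static SEXP read_double_attr(hid_t loc, const char *name)
{
    if (H5Aexists(loc, name) <= 0) return R_NilValue;
    hid_t attr = H5Aopen(loc, name, H5P_DEFAULT);
    double v = 0;
    H5Aread(attr, H5T_NATIVE_DOUBLE, &v);
    H5Aclose(attr);
    return Rf_ScalarReal(v);
}

/* kspace: complex array, R dim c(kx, ky, coils, slices); rss: double array
 * with R dim c(kx, ky, slices) or NULL. */
SEXP C_h5_write_scan(SEXP path, SEXP kspace, SEXP rss,
                     SEXP scanner, SEXP split, SEXP scale_factor)
{
    const char *fname = CHAR(STRING_ELT(path, 0));
    SEXP kdim = Rf_getAttrib(kspace, R_DimSymbol);
    if (Rf_length(kdim) != 4 || !Rf_isComplex(kspace))
        Rf_error("internal: kspace buffer must be a 4-D complex array");
    int *kd = INTEGER(kdim);
    hsize_t dims[4] = { (hsize_t) kd[3], (hsize_t) kd[2],
                        (hsize_t) kd[1], (hsize_t) kd[0] };

    hid_t file = H5Fcreate(fname, H5F_ACC_TRUNC, H5P_DEFAULT, H5P_DEFAULT);
    if (file < 0) Rf_error("cannot create HDF5 file '%s'", fname);

    hid_t ctype = complex_memtype();
    hid_t space = H5Screate_simple(4, dims, NULL);
    hid_t dset = H5Dcreate2(file, "kspace", ctype, space,
                            H5P_DEFAULT, H5P_DEFAULT, H5P_DEFAULT);
    herr_t st = H5Dwrite(dset, ctype, H5S_ALL, H5S_ALL, H5P_DEFAULT,
                         COMPLEX(kspace));
    H5Dclose(dset); H5Sclose(space); H5Tclose(ctype);
    if (st < 0) { H5Fclose(file); Rf_error("failed writing dataset 'kspace'"); }

    if (!Rf_isNull(rss)) {
        SEXP rdim = Rf_getAttrib(rss, R_DimSymbol);
        if (Rf_length(rdim) != 3 || !Rf_isReal(rss))
            Rf_error("internal: rss buffer must be a 3-D double array");
        int *rd = INTEGER(rdim);
        hsize_t rdims[3] = { (hsize_t) rd[2], (hsize_t) rd[1], (hsize_t) rd[0] };
        hid_t rspace = H5Screate_simple(3, rdims, NULL);
        hid_t rdset = H5Dcreate2(file, "reconstruction_rss", H5T_NATIVE_DOUBLE,
                                 rspace, H5P_DEFAULT, H5P_DEFAULT, H5P_DEFAULT);
        st = H5Dwrite(rdset, H5T_NATIVE_DOUBLE, H5S_ALL, H5S_ALL, H5P_DEFAULT,
                      REAL(rss));
        H5Dclose(rdset); H5Sclose(rspace);
        if (st < 0) { H5Fclose(file); Rf_error("failed writing 'reconstruction_rss'"); }
    }

    hid_t root = H5Gopen2(file, "/", H5P_DEFAULT);
    write_string_attr(root, "scanner", CHAR(STRING_ELT(scanner, 0)));
    write_string_attr(root, "split", CHAR(STRING_ELT(split, 0)));
    write_double_attr(root, "scale_factor", Rf_asReal(scale_factor));
    H5Gclose(root);
    H5Fclose(file);
    return R_NilValue;
}

SEXP C_h5_read_scan(SEXP path)
{
    const char *fname = CHAR(STRING_ELT(path, 0));
    hid_t file = H5Fopen(fname, H5F_ACC_RDONLY, H5P_DEFAULT);
    if (file < 0) Rf_error("cannot open HDF5 file '%s'", fname);

    if (H5Lexists(file, "kspace", H5P_DEFAULT) <= 0) {
        H5Fclose(file);
        Rf_error("format error: file '%s' lacks dataset 'kspace'", fname);
    }
    hid_t dset = H5Dopen2(file, "kspace", H5P_DEFAULT);
    hid_t ftype = H5Tget_class(H5Dget_type(dset));
    if (ftype != H5T_COMPOUND) {
        H5Dclose(dset); H5Fclose(file);
        Rf_error("format error: dataset 'kspace' is not stored as complex (compound {r,i})");
    }
    hid_t space = H5Dget_space(dset);
    int rank = H5Sget_simple_extent_ndims(space);
    if (rank != 4) {
        H5Sclose(space); H5Dclose(dset); H5Fclose(file);
        Rf_error("format error: dataset 'kspace' has %d axes, expected 4 (slices x coils x ky x kx)",
                 rank);
    }
    hsize_t dims[4];
    H5Sget_simple_extent_dims(space, dims, NULL);
    H5Sclose(space);

    R_xlen_t n = (R_xlen_t)(dims[0] * dims[1] * dims[2] * dims[3]);
    SEXP kspace = PROTECT(Rf_allocVector(CPLXSXP, n));
    hid_t ctype = complex_memtype();
    herr_t st = H5Dread(dset, ctype, H5S_ALL, H5S_ALL, H5P_DEFAULT,
                        COMPLEX(kspace));
    H5Tclose(ctype); H5Dclose(dset);
    if (st < 0) { H5Fclose(file); Rf_error("failed reading dataset 'kspace'"); }
    SEXP kdim = PROTECT(Rf_allocVector(INTSXP, 4));
    INTEGER(kdim)[0] = (int) dims[3]; INTEGER(kdim)[1] = (int) dims[2];
    INTEGER(kdim)[2] = (int) dims[1]; INTEGER(kdim)[3] = (int) dims[0];
    Rf_setAttrib(kspace, R_DimSymbol, kdim);

    SEXP rss = R_NilValue;
    PROTECT_INDEX rpi;
    PROTECT_WITH_INDEX(rss, &rpi);
    if (H5Lexists(file, "reconstruction_rss", H5P_DEFAULT) > 0) {
        hid_t rdset = H5Dopen2(file, "reconstruction_rss", H5P_DEFAULT);
        hid_t rspace = H5Dget_space(rdset);
        if (H5Sget_simple_extent_ndims(rspace) == 3) {
            hsize_t rdims[3];
            H5Sget_simple_extent_dims(rspace, rdims, NULL);
            R_xlen_t rn = (R_xlen_t)(rdims[0] * rdims[1] * rdims[2]);
            REPROTECT(rss = Rf_allocVector(REALSXP, rn), rpi);
            H5Dread(rdset, H5T_NATIVE_DOUBLE, H5S_ALL, H5S_ALL, H5P_DEFAULT,
                    REAL(rss));
            SEXP rdim = PROTECT(Rf_allocVector(INTSXP, 3));
            INTEGER(rdim)[0] = (int) rdims[2]; INTEGER(rdim)[1] = (int) rdims[1];
            INTEGER(rdim)[2] = (int) rdims[0];
            Rf_setAttrib(rss, R_DimSymbol, rdim);
            UNPROTECT(1);
        }
        H5Sclose(rspace); H5Dclose(rdset);
    }

    hid_t root = H5Gopen2(file, "/", H5P_DEFAULT);
    SEXP scanner = PROTECT(read_string_attr(root, "scanner"));
    SEXP splitlab = PROTECT(read_string_attr(root, "split"));
    SEXP scale = PROTECT(read_double_attr(root, "scale_factor"));
    H5Gclose(root);
    H5Fclose(file);

    const char *nm[] = {"kspace", "rss", "scanner", "split", "scale_factor", ""};
    SEXP out = PROTECT(Rf_mkNamed(VECSXP, nm));
    SET_VECTOR_ELT(out, 0, kspace);
    SET_VECTOR_ELT(out, 1, rss);
    SET_VECTOR_ELT(out, 2, scanner);
    SET_VECTOR_ELT(out, 3, splitlab);
    SET_VECTOR_ELT(out, 4, scale);
    UNPROTECT(7);
    return out;
}
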
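# OneOPES replica input (PLUMED 2.9 dialect)
# replica 3 of 8
# Funnel restraint composition: axial projection fz and radial
# distance frho from the funnel origin; allowed radius
# R(z) = Rcyl + tan(alpha)*max(0, zcc - z); harmonic UPPER_WALLS on
# the radial excess. Mirrored '_b' blocks appear for dual funnels.
UNITS LENGTH=nm ENERGY=kj/mol

lig: COM ATOMS=1,2,3,4,5
fo_z: FIXEDATOM AT=0,0,0
d_z: DISTANCE ATOMS=fo_z,lig COMPONENTS
z: COMBINE ARG=d_z.x,d_z.y,d_z.z COEFFICIENTS=0,0,1 PERIODIC=NO

ax_COS: DISTANCE ATOMS=1,5 COMPONENTS
n_COS: CUSTOM ARG=ax_COS.x,ax_COS.y,ax_COS.z FUNC=sqrt(x*x+y*y+z*z) PERIODIC=NO
COS: CUSTOM ARG=ax_COS.x,ax_COS.y,ax_COS.z,n_COS FUNC=(x*0+y*0+z*1)/t VAR=x,y,z,t PERIODIC=NO

WL4: COORDINATION GROUPA=2 GROUPB=@water_oxygens SWITCH={RATIONAL R_0=0.25 D_MAX=0.08 NN=6 MM=10} NLIST NL_CUTOFF=0.15 NL_STRIDE=20

t2: TORSION ATOMS=2,3,4,5

t3: TORSION ATOMS=3,4,5,6

vp_WH1: FIXEDATOM AT=0,0,0.1
WH1: COORDINATION GROUPA=vp_WH1 GROUPB=@water_oxygens SWITCH={RATIONAL R_0=0.25 D_MAX=0.08 NN=2 MM=6} NLIST NL_CUTOFF=0.15 NL_STRIDE=20

t1: TORSION ATOMS=1,2,3,4

WL1: COORDINATION GROUPA=2 GROUPB=@water_oxygens SWITCH={RATIONAL R_0=0.25 D_MAX=0.08 NN=6 MM=10} NLIST NL_CUTOFF=0.15 NL_STRIDE=20

fc_a: FIXEDATOM AT=0,0,0
fd_a: DISTANCE ATOMS=fc_a,lig COMPONENTS
fz_a: COMBINE ARG=fd_a.x,fd_a.y,fd_a.z COEFFICIENTS=0,0,1 PERIODIC=NO
frho_a: CUSTOM ARG=fd_a.x,fd_a.y,fd_a.z,fz_a FUNC=sqrt(x*x+y*y+z*z-t*t) VAR=x,y,z,t PERIODIC=NO
fexc_a: CUSTOM ARG=frho_a,fz_a FUNC=y-(0.2+0.684137*max(0,0.4-x)) VAR=y,x PERIODIC=NO
fwall_a: UPPER_WALLS ARG=fexc_a AT=0 KAPPA=1000 EXP=2 LABEL_SUFFIX=a
fc_b: FIXEDATOM AT=0,0,0
fd_b: DISTANCE ATOMS=fc_b,lig COMPONENTS
fz_b: COMBINE ARG=fd_b.x,fd_b.y,fd_b.z COEFFICIENTS=0,0,-1 PERIODIC=NO
frho_b: CUSTOM ARG=fd_b.x,fd_b.y,fd_b.z,fz_b FUNC=sqrt(x*x+y*y+z*z-t*t) VAR=x,y,z,t PERIODIC=NO
fexc_b: CUSTOM ARG=frho_b,fz_b FUNC=y-(0.2+0.684137*max(0,0.4-x)) VAR=y,x PERIODIC=NO
fwall_b: UPPER_WALLS ARG=fexc_b AT=0 KAPPA=1000 EXP=2 LABEL_SUFFIX=b

opes_main: OPES_METAD_EXPLORE ARG=z,COS PACE=10000 BARRIER=100 SIGMA=0.05,0.1 TEMP=298
opes_multicv1: OPES_METAD_EXPLORE ARG=WL4,t2,t3 PACE=20000 BARRIER=3 TEMP=298
opes_multicv2: OPES_METAD_EXPLORE ARG=WH1,t3,t1 PACE=20000 BARRIER=3 TEMP=298
opes_multicv3: OPES_METAD_EXPLORE ARG=WL1,t1,t2 PACE=20000 BARRIER=3 TEMP=298

PRINT ARG=z,COS,WL4,t2,t3,WH1,t1,WL1,*.bias STRIDE=500 FILE=COLVAR
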
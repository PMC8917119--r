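column,type,unit,required,description
patient_id,character,,TRUE,Opaque patient identifier
eye_id,character,,TRUE,"Opaque eye identifier, unique per row"
laterality,character,,TRUE,OD (right) or OS (left)
age,numeric,year,TRUE,"Age at surgery, in (0, 120)"
sex,character,,TRUE,M or F
axial_length,numeric,mm,TRUE,"Axial length, in (15, 40)"
iol_power,numeric,D,TRUE,Implanted IOL spherical power
preop_flat_k_24,numeric,D,TRUE,Preoperative flattest keratometry at the 2.4-mm zone
preop_steep_k_24,numeric,D,TRUE,Preoperative steepest keratometry at the 2.4-mm zone
preop_steep_axis_24,numeric,degree,TRUE,Preoperative steep-meridian axis at the 2.4-mm zone
preop_flat_k_33,numeric,D,TRUE,Preoperative flattest keratometry at the 3.3-mm zone
preop_steep_k_33,numeric,D,TRUE,Preoperative steepest keratometry at the 3.3-mm zone
preop_steep_axis_33,numeric,degree,TRUE,Preoperative steep-meridian axis at the 3.3-mm zone
postop_flat_k_24,numeric,D,TRUE,Postoperative flattest keratometry at the 2.4-mm zone
postop_steep_k_24,numeric,D,TRUE,Postoperative steepest keratometry at the 2.4-mm zone
postop_steep_axis_24,numeric,degree,TRUE,Postoperative steep-meridian axis at the 2.4-mm zone
postop_flat_k_33,numeric,D,TRUE,Postoperative flattest keratometry at the 3.3-mm zone
postop_steep_k_33,numeric,D,TRUE,Postoperative steepest keratometry at the 3.3-mm zone
postop_steep_axis_33,numeric,degree,TRUE,Postoperative steep-meridian axis at the 3.3-mm zone
ref_sphere,numeric,D,TRUE,Postoperative manifest sphere (spectacle plane)
ref_cylinder,numeric,D,TRUE,Postoperative manifest cylinder (spectacle plane)
ref_axis,numeric,degree,TRUE,Manifest cylinder axis
corneal_irregularity,numeric,,FALSE,Scheimpflug corneal irregularity index
bcva_decimal,numeric,,FALSE,"Postoperative best corrected visual acuity, decimal"
prior_refractive_surgery,logical,,FALSE,History of refractive/intraocular surgery
complication,logical,,FALSE,Intra- or postoperative complication
corneal_opacity,logical,,FALSE,Corneal opacity
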
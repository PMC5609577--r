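preset,class,lipid,mean_mgdl,cv
low_hdl_cm,CM01,CH,2.93,0.45
low_hdl_cm,CM02,CH,1.81,0.45
low_hdl_cm,VLDL03,CH,5.70,0.35
low_hdl_cm,VLDL04,CH,8.20,0.35
low_hdl_cm,VLDL05,CH,22.06,0.35
low_hdl_cm,VLDL06,CH,10.86,0.35
low_hdl_cm,VLDL07,CH,8.51,0.35
low_hdl_cm,LDL08,CH,31.69,0.25
low_hdl_cm,LDL09,CH,54.82,0.25
low_hdl_cm,LDL10,CH,21.98,0.25
low_hdl_cm,LDL11,CH,6.12,0.25
low_hdl_cm,LDL12,CH,2.50,0.25
low_hdl_cm,LDL13,CH,1.20,0.25
low_hdl_cm,HDL14,CH,0.60,0.20
low_hdl_cm,HDL15,CH,1.31,0.20
low_hdl_cm,HDL16,CH,4.08,0.20
low_hdl_cm,HDL17,CH,15.25,0.20
low_hdl_cm,HDL18,CH,16.21,0.20
low_hdl_cm,HDL19,CH,3.00,0.20
low_hdl_cm,HDL20,CH,1.50,0.20
low_hdl_cm,CM01,TG,12.02,0.45
low_hdl_cm,CM02,TG,8.40,0.45
low_hdl_cm,VLDL03,TG,21.13,0.35
low_hdl_cm,VLDL04,TG,31.03,0.35
low_hdl_cm,VLDL05,TG,31.56,0.35
low_hdl_cm,VLDL06,TG,13.26,0.35
low_hdl_cm,VLDL07,TG,5.83,0.35
low_hdl_cm,LDL08,TG,9.81,0.25
low_hdl_cm,LDL09,TG,9.55,0.25
low_hdl_cm,LDL10,TG,3.71,0.25
low_hdl_cm,LDL11,TG,1.24,0.25
low_hdl_cm,LDL12,TG,0.80,0.25
low_hdl_cm,LDL13,TG,0.50,0.25
low_hdl_cm,HDL14,TG,0.30,0.20
low_hdl_cm,HDL15,TG,0.44,0.20
low_hdl_cm,HDL16,TG,1.77,0.20
low_hdl_cm,HDL17,TG,4.95,0.20
low_hdl_cm,HDL18,TG,3.98,0.20
low_hdl_cm,HDL19,TG,1.00,0.20
low_hdl_cm,HDL20,TG,0.60,0.20
hyperchol,CM01,CH,0.10,0.50
hyperchol,CM02,CH,0.10,0.50
hyperchol,VLDL03,CH,2.00,0.35
hyperchol,VLDL04,CH,3.50,0.35
hyperchol,VLDL05,CH,12.00,0.35
hyperchol,VLDL06,CH,10.90,0.35
hyperchol,VLDL07,CH,8.50,0.35
hyperchol,LDL08,CH,38.00,0.25
hyperchol,LDL09,CH,57.00,0.25
hyperchol,LDL10,CH,23.00,0.25
hyperchol,LDL11,CH,6.50,0.25
hyperchol,LDL12,CH,2.20,0.25
hyperchol,LDL13,CH,1.10,0.25
hyperchol,HDL14,CH,0.80,0.20
hyperchol,HDL15,CH,3.50,0.20
hyperchol,HDL16,CH,8.00,0.20
hyperchol,HDL17,CH,20.00,0.20
hyperchol,HDL18,CH,16.20,0.20
hyperchol,HDL19,CH,3.00,0.20
hyperchol,HDL20,CH,1.50,0.20
hyperchol,CM01,TG,0.20,0.50
hyperchol,CM02,TG,0.15,0.50
hyperchol,VLDL03,TG,8.00,0.35
hyperchol,VLDL04,TG,15.00,0.35
hyperchol,VLDL05,TG,20.00,0.35
hyperchol,VLDL06,TG,13.30,0.35
hyperchol,VLDL07,TG,5.80,0.35
hyperchol,LDL08,TG,9.80,0.25
hyperchol,LDL09,TG,9.50,0.25
hyperchol,LDL10,TG,3.70,0.25
hyperchol,LDL11,TG,1.20,0.25
hyperchol,LDL12,TG,0.80,0.25
hyperchol,LDL13,TG,0.50,0.25
hyperchol,HDL14,TG,0.30,0.20
hyperchol,HDL15,TG,0.50,0.20
hyperchol,HDL16,TG,2.50,0.20
hyperchol,HDL17,TG,3.80,0.20
hyperchol,HDL18,TG,3.00,0.20
hyperchol,HDL19,TG,0.80,0.20
hyperchol,HDL20,TG,0.50,0.20
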
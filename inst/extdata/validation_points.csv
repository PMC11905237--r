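# Point-dose validation fixture: ion-chamber (measured), TPS and secondary-
# calculation doses for 100 MU in homogeneous water, Elekta Unity 7X-FFF.
# Jaw spec: "X,Y" widths in cm, or "[x1,x2],Y" asymmetric X edges in cm with
# centered Y width. Points (x,y,z) cm: cross-plane, in-plane, depth.
ssd_cm,jaws,x_cm,y_cm,z_cm,measured_cgy,tps_cgy,clearcalc_cgy
133.5,"10,10",0,0,10,86.5,86.1,85.6
133.5,"5,20",0,0,5,105.6,105.7,105.0
133.5,"5,20",0,5,5,96.3,97.0,95.6
133.5,"5,20",0,0,13,72.5,72.1,72.1
133.5,"20,5",0,0,5,105.8,105.4,105.5
133.5,"20,5",-5,0,5,96.5,96.3,95.8
133.5,"20,5",0,0,13,72.6,72.1,71.9
133.5,"4,4",0,0,5,100.2,99.9,99.4
133.5,"4,4",0,0,13,66.3,65.5,64.6
133.5,"50,22",0,0,13,87.6,87.1,87.3
133.5,"50,22",12.5,0,13,65.4,64.9,63.7
133.5,"50,22",0,5,13,80.9,80.6,79.3
133.5,"50,22",-12.5,0,13,64.7,64.4,63.9
133.5,"50,22",0,-5,13,81.8,80.7,79.3
138.5,"10,10",0,0,5,100.5,100.2,100
138.5,"[-10,20],10",15,0,5,65.8,64.8,66.8
138.5,"[-10,20],10",16.5,0,8,55.5,54.9,56.7
138.5,"[20,-10],10",-15,0,5,65.1,64.5,66.3
138.5,"[20,-10],10",-16.5,0,8,54.8,54.3,56.4
143.5,"2,2",0,0,1,94.7,95.6,95.7
143.5,"2,2",0,0,3,87.8,89.8,86.7
143.5,"3,3",0,0,1,100.1,99.4,97.4
143.5,"50,22",0,0,1,116.7,115.8,117.7
143.5,"50,22",0,5,3,103.3,104.0,105.2
143.5,"50,22",0,-5,3,104.4,104.0,105.1
143.5,"50,22",12.5,0,3,82.8,82.7,83.5
143.5,"50,22",-12.5,5,3,79.2,79.2,80.4
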